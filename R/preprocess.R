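# Sample QC, probe-to-gene collapsing, low-expression filtering and
# age-interval partitioning.
#
# Ages live on a unified axis of postnatal years: prenatal ages given in
# weeks postconception (WPC) are converted with birth fixed at 38 WPC, so
# 10 WPC maps to (10 - 38) / 52 ~ -0.54 years. The default interval scheme
# covers prenatal development (I-1), early childhood to age 6 (I-2),
# ages 6-40 (I-3, peak cortical myelination) and 40 onwards (I-4).

WEEKS_PER_YEAR <- 52
BIRTH_WPC <- 38

#' Developmental age-interval scheme
#'
#' An ordered set of half-open intervals `[lower, upper)` on the unified age
#' axis (postnatal years; prenatal ages are negative). The default is the
#' four-interval scheme used for developmental brain transcriptome work:
#' I-1 from 10 weeks postconception to birth, I-2 birth to <6 years,
#' I-3 6 to <40 years, I-4 40 years on.
#'
#' @param labels character vector of interval labels.
#' @param lower,upper numeric vectors of inclusive lower / exclusive upper
#'   bounds in postnatal years.
#' @return a data.frame of class `interval_scheme`.
#' @export
interval_scheme <- function(labels = c("I-1", "I-2", "I-3", "I-4"),
                            lower = c((10 - BIRTH_WPC) / WEEKS_PER_YEAR,
                                      0, 6, 40),
                            upper = c(0, 6, 40, Inf)) {
  stopifnot(length(labels) == length(lower),
            length(lower) == length(upper), all(lower < upper))
  if (is.unsorted(lower) || any(upper[-length(upper)] > lower[-1]))
    stop("intervals must be ordered and disjoint", call. = FALSE)
  structure(data.frame(label = labels, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("interval_scheme", "data.frame"))
}

#' Read an interval scheme from YAML
#'
#' Expects a top-level `intervals:` list whose entries have `label`, `lower`
#' and `upper` (years; `.inf` allowed). A shipped default is at
#' `system.file("extdata", "intervals_default.yaml", package = "coexdev")`.
#'
#' @param path YAML file path.
#' @return an [interval_scheme()].
#' @export
read_interval_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  iv <- y$intervals
  interval_scheme(labels = vapply(iv, `[[`, "", "label"),
                  lower = vapply(iv, function(i) as.numeric(i$lower), 0),
                  upper = vapply(iv, function(i) as.numeric(i$upper), 0))
}

#' Convert ages to the unified postnatal-years axis
#'
#' @param age_value nonnegative ages.
#' @param age_unit per-sample unit, `"weeks_postconception"` or `"years"`.
#' @return numeric vector in postnatal years (prenatal ages negative).
#' @export
unified_age <- function(age_value, age_unit) {
  if (any(age_value < 0)) stop("negative age", call. = FALSE)
  stopifnot(all(age_unit %in% c("weeks_postconception", "years")))
  ifelse(age_unit == "weeks_postconception",
         (age_value - BIRTH_WPC) / WEEKS_PER_YEAR, age_value)
}

#' Assign samples to age intervals
#'
#' Every sample maps to exactly one interval; samples whose ages fall outside
#' all intervals are flagged `NA` (never silently dropped) with a warning.
#'
#' @param samples data.frame with `sample_id`, `age_value`, `age_unit`.
#' @param scheme an [interval_scheme()].
#' @return named character vector, sample_id -> interval label (or `NA`).
#' @export
assign_intervals <- function(samples, scheme = interval_scheme()) {
  age <- unified_age(samples$age_value, samples$age_unit)
  lab <- rep(NA_character_, nrow(samples))
  for (i in seq_len(nrow(scheme)))
    lab[age >= scheme$lower[i] & age < scheme$upper[i]] <- scheme$label[i]
  names(lab) <- samples$sample_id
  if (anyNA(lab))
    warning(sum(is.na(lab)), " sample(s) fall outside all intervals",
            call. = FALSE)
  lab
}

#' Filtering configuration
#'
#' @param min_log2_intensity minimum log2 expression a gene must reach in
#'   every (region x interval) group to be kept (inclusive).
#' @param min_RIN minimum RNA integrity number for sample QC (inclusive).
#' @param per_sample if `FALSE` (default) the expression rule applies to the
#'   group mean; if `TRUE`, to every individual sample in the group.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_log2_intensity = 6, min_RIN = 8,
                          per_sample = FALSE) {
  stopifnot(is.finite(min_log2_intensity), is.finite(min_RIN))
  structure(list(min_log2_intensity = min_log2_intensity,
                 min_RIN = min_RIN, per_sample = per_sample),
            class = "filter_config")
}

#' Collapse a probe-level matrix to one row per gene
#'
#' For genes measured by several probes the representative probe is the one
#' with the highest mean intensity across samples (the max-mean rule).
#' Probes without a gene mapping are dropped.
#'
#' @param probe_matrix numeric matrix, probes x samples, probe rownames.
#' @param probe_to_gene data.frame with columns `probe` and `gene` (or a
#'   named character vector probe -> gene).
#' @return numeric matrix, genes x samples.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  if (is.character(probe_to_gene) && !is.null(names(probe_to_gene)))
    probe_to_gene <- data.frame(probe = names(probe_to_gene),
                                gene = unname(probe_to_gene),
                                stringsAsFactors = FALSE)
  if (nrow(probe_to_gene) == 0) stop("empty probe-to-gene mapping",
                                     call. = FALSE)
  map <- probe_to_gene[probe_to_gene$probe %in% rownames(probe_matrix) &
                       !is.na(probe_to_gene$gene) &
                       nzchar(probe_to_gene$gene), , drop = FALSE]
  if (anyDuplicated(map$probe))
    stop("a probe maps to more than one gene", call. = FALSE)
  means <- rowMeans(probe_matrix)[map$probe]
  keep <- unlist(lapply(split(seq_len(nrow(map)), map$gene), function(idx)
    idx[which.max(means[idx])]))
  out <- probe_matrix[map$probe[keep], , drop = FALSE]
  rownames(out) <- map$gene[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Drop samples that fail RNA-quality control
#'
#' Retains samples with `RIN >= min_RIN` (inclusive).
#'
#' @param samples data.frame with an `RIN` column.
#' @param cfg a [filter_config()].
#' @return the filtered sample table.
#' @export
filter_samples <- function(samples, cfg = filter_config()) {
  if (is.null(samples$RIN) || anyNA(samples$RIN))
    stop("RIN missing for one or more samples", call. = FALSE)
  samples[samples$RIN >= cfg$min_RIN, , drop = FALSE]
}

#' Keep genes consistently expressed in all region-interval groups
#'
#' A gene is kept iff its summary intensity is at least
#' `min_log2_intensity` in every (region x interval) group (inclusive).
#' The summary is the group mean by default, or the group minimum when
#' `cfg$per_sample` is `TRUE`. Row order is preserved.
#'
#' @param expr genes x samples matrix; columns must appear in `samples`.
#' @param samples sample table with `sample_id`, ages and (optionally) a
#'   `region` column; a missing region column is treated as one region.
#' @param cfg a [filter_config()].
#' @param scheme an [interval_scheme()] used to group samples by age.
#' @return the filtered expression matrix.
#' @export
filter_genes <- function(expr, samples, cfg = filter_config(),
                         scheme = interval_scheme()) {
  if (!all(colnames(expr) %in% samples$sample_id))
    stop("matrix columns not all present in the sample table", call. = FALSE)
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  interval <- assign_intervals(samples, scheme)
  region <- if (is.null(samples$region)) rep("all", nrow(samples))
            else samples$region
  grp <- paste(region, interval, sep = " x ")
  expected <- as.vector(outer(unique(region), scheme$label, paste,
                              sep = " x "))
  missing_grp <- setdiff(expected, grp)
  if (length(missing_grp))
    stop("empty region x interval group(s): ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  groups <- split(seq_along(grp), grp)
  summ <- lapply(groups, function(idx) {
    sub <- expr[, idx, drop = FALSE]
    if (cfg$per_sample) apply(sub, 1, min) else rowMeans(sub)
  })
  keep <- Reduce(`&`, lapply(summ, `>=`, cfg$min_log2_intensity))
  expr[keep, , drop = FALSE]
}
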