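# Study orchestration: run the network fit, trait correlations, marker
# enrichment and the risk-list bootstrap per age interval, then match
# module labels across intervals against the first interval's network.

#' Study configuration
#'
#' Bundles all per-interval analysis settings.
#'
#' @param interval_scheme an [interval_scheme()].
#' @param filter a [filter_config()].
#' @param network a [network_config()].
#' @param treecut a [treecut_config()].
#' @param gene_of_interest gene identifier whose module is followed across
#'   intervals and tested against the risk list (default `"DDR1"`).
#' @param bootstrap_B bootstrap replicates for the risk-list test.
#' @param match_p_threshold significance threshold for cross-interval
#'   module label matching.
#' @param seed integer seed for the bootstrap null.
#' @return a list of class `study_config`.
#' @export
study_config <- function(interval_scheme = coexdev::interval_scheme(),
                         filter = filter_config(),
                         network = network_config(),
                         treecut = treecut_config(),
                         gene_of_interest = "DDR1",
                         bootstrap_B = 10000,
                         match_p_threshold = 0.05,
                         seed = 1L) {
  structure(list(interval_scheme = interval_scheme, filter = filter,
                 network = network, treecut = treecut,
                 gene_of_interest = gene_of_interest,
                 bootstrap_B = as.integer(bootstrap_B),
                 match_p_threshold = match_p_threshold,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Analyse one age interval end to end
#'
#' Fits the coexpression network ([coexnet()]), computes eigengene-trait
#' correlations, tests every module against the marker collection
#' (Bonferroni within this interval), locates the gene of interest and runs
#' the bootstrap risk-list overlap test on its module. If the gene of
#' interest is absent (or in module 0) the bootstrap is skipped with a
#' warning.
#'
#' @param expr genes x samples matrix for this interval's samples.
#' @param samples sample table (traits for the ME correlations).
#' @param cfg a [study_config()].
#' @param markers named list of marker gene sets (may be empty).
#' @param risk_list character vector of risk genes (may be `NULL`).
#' @param label interval label used in reporting.
#' @return list of class `interval_report`: `label`, `fit` (the `coexnet`),
#'   `power`, `n_modules`, `modules`, `trait_correlations`, `enrichment`,
#'   `goi_module` (label, `NA` if absent, 0 if background), `bootstrap`
#'   (a `bootstrap_overlap` or `NULL`).
#' @export
run_interval <- function(expr, samples, cfg = study_config(),
                         markers = list(), risk_list = NULL,
                         label = "interval") {
  if (ncol(expr) < 8)
    stop("interval '", label, "' has fewer than 8 samples", call. = FALSE)
  if (ncol(expr) < 15)
    warning("interval '", label, "' has fewer than 15 samples; ",
            "correlations will be noisy", call. = FALSE)
  fit <- coexnet(expr, network = cfg$network, treecut = cfg$treecut)
  mods <- modules(fit)
  background <- rownames(expr)

  traits <- if (length(fit$eigengenes) && ncol(samples) > 1)
    eigengene_trait_correlation(fit$eigengenes, samples)
  else data.frame()

  enrichment <- if (length(markers)) {
    restricted <- suppressWarnings(
      restrict_to_background(markers, background))
    hypergeom_enrichment(mods, restricted, background)
  } else data.frame()

  goi <- cfg$gene_of_interest
  goi_module <- if (goi %in% names(mods)) unname(mods[goi]) else NA_integer_
  boot <- NULL
  if (!is.null(risk_list)) {
    if (is.na(goi_module)) {
      warning("gene of interest '", goi, "' absent from interval '",
              label, "'; bootstrap skipped", call. = FALSE)
    } else if (goi_module == 0L) {
      warning("gene of interest '", goi, "' is background in interval '",
              label, "'; bootstrap skipped", call. = FALSE)
    } else {
      boot <- bootstrap_overlap(names(mods)[mods == goi_module],
                                risk_list, background,
                                B = cfg$bootstrap_B, seed = cfg$seed)
    }
  }
  structure(list(label = label, fit = fit, power = fit$power,
                 n_modules = length(setdiff(unique(mods), 0L)),
                 modules = mods, trait_correlations = traits,
                 enrichment = enrichment, goi_module = goi_module,
                 bootstrap = boot),
            class = "interval_report")
}

#' @export
print.interval_report <- function(x, ...) {
  cat("Interval ", x$label, ": power ", x$power, ", ", x$n_modules,
      " modules; gene of interest in module ",
      if (is.na(x$goi_module)) "absent" else x$goi_module, sep = "")
  if (!is.null(x$bootstrap))
    cat("; risk-list overlap ", x$bootstrap$observed,
        " (empirical p = ", format(x$bootstrap$empirical_p), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Run the full multi-interval study
#'
#' Splits the samples by age interval, analyses each interval independently
#' with [run_interval()], then relabels every interval's modules against
#' the first interval's network via [match_labels()] so the gene of
#' interest's module is traceable across development. An interval that
#' errors produces a stub report and the study continues.
#'
#' @param expr genes x samples matrix covering all samples.
#' @param samples sample table with `sample_id`, `age_value`, `age_unit`,
#'   optionally `RIN` and trait columns.
#' @param cfg a [study_config()].
#' @param markers named list of marker gene sets.
#' @param risk_list character vector of risk genes.
#' @return list of class `coexnet_study`: `reports` (per interval),
#'   `summary` (data.frame: interval, power, modules, gene-of-interest
#'   module before and after matching, bootstrap overlap and p),
#'   `matching` (per-interval audit trails).
#' @export
run_study <- function(expr, samples, cfg = study_config(),
                      markers = list(), risk_list = NULL) {
  if (!is.null(samples$RIN)) samples <- filter_samples(samples, cfg$filter)
  iv <- assign_intervals(samples, cfg$interval_scheme)
  iv <- iv[!is.na(iv)]
  labels <- cfg$interval_scheme$label[cfg$interval_scheme$label %in% iv]
  if (length(labels) == 0) stop("no interval has data", call. = FALSE)

  reports <- list()
  for (lab in labels) {
    ids <- intersect(colnames(expr), names(iv)[iv == lab])
    reports[[lab]] <- tryCatch(
      run_interval(expr[, ids, drop = FALSE],
                   samples[samples$sample_id %in% ids, , drop = FALSE],
                   cfg, markers = markers, risk_list = risk_list,
                   label = lab),
      error = function(e) structure(list(label = lab, error = conditionMessage(e)),
                                    class = "interval_report"))
  }

  ok <- !vapply(reports, function(r) !is.null(r$error), logical(1))
  matching <- list()
  matched_goi <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  if (any(ok)) {
    ref_lab <- labels[ok][1]
    ref <- reports[[ref_lab]]$modules
    for (lab in labels[ok]) {
      if (lab == ref_lab) {
        matched <- reports[[lab]]$modules
        matching[[lab]] <- NULL
      } else {
        ml <- match_labels(ref, reports[[lab]]$modules,
                           cfg$match_p_threshold)
        matched <- ml$assignment
        matching[[lab]] <- ml$pairs
      }
      reports[[lab]]$modules_matched <- matched
      goi <- cfg$gene_of_interest
      matched_goi[lab] <- if (goi %in% names(matched))
        unname(matched[goi]) else NA_integer_
    }
  }

  summary_tab <- data.frame(
    interval = labels,
    power = vapply(reports, function(r)
      if (is.null(r$error)) r$power else NA_integer_, 1L),
    n_modules = vapply(reports, function(r)
      if (is.null(r$error)) r$n_modules else NA_integer_, 1L),
    goi_module = vapply(reports, function(r)
      if (is.null(r$error)) r$goi_module else NA_integer_, 1L),
    goi_module_matched = matched_goi,
    risk_overlap = vapply(reports, function(r)
      if (!is.null(r$bootstrap)) r$bootstrap$observed else NA_integer_, 1L),
    empirical_p = vapply(reports, function(r)
      if (!is.null(r$bootstrap)) r$bootstrap$empirical_p else NA_real_, 1.0),
    row.names = NULL)

  structure(list(reports = reports, summary = summary_tab,
                 matching = matching, config = cfg),
            class = "coexnet_study")
}

#' @export
print.coexnet_study <- function(x, ...) {
  cat("Coexpression study over", nrow(x$summary), "interval(s); gene of",
      "interest:", x$config$gene_of_interest, "\n\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write study outputs as TSV tables
#'
#' Persists the per-interval module assignments (matched labels where
#' available), trait correlations, enrichment tables, bootstrap summaries
#' and the study summary, one file per table.
#'
#' @param study a `coexnet_study`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(study$summary, "summary.tsv")
  for (r in study$reports) {
    if (!is.null(r$error)) next
    mods <- if (!is.null(r$modules_matched)) r$modules_matched else r$modules
    wt(data.frame(gene_id = names(mods), module = unname(mods),
                  color = module_colors(unname(mods))),
       paste0("modules_", r$label, ".tsv"))
    if (nrow(r$trait_correlations))
      wt(r$trait_correlations, paste0("trait_cor_", r$label, ".tsv"))
    if (NROW(r$enrichment))
      wt(r$enrichment, paste0("enrichment_", r$label, ".tsv"))
  }
  invisible(dir)
}
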