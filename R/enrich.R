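# Gene-set enrichment of modules (hypergeometric upper tail, Bonferroni
# across all module x list tests) and the bootstrap empirical-null overlap
# test of a module against a risk-gene list.

#' Upper-tail hypergeometric overlap p-value
#'
#' `P(X >= x)` for `X` hypergeometric with population size `N`, `l`
#' successes and `m` draws — the probability that a random set of `m` genes
#' from a background of `N` overlaps a list of `l` genes in at least `x`.
#' The tail is inclusive of the observed overlap.
#'
#' @param x observed overlap.
#' @param m module (draw) size.
#' @param l list size within the background.
#' @param N background size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_tail_p <- function(x, m, l, N) {
  stopifnot(x >= 0, m >= 0, l >= 0, N >= m, N >= l, x <= min(m, l))
  stats::phyper(x - 1, l, N - l, m, lower.tail = FALSE)
}

#' Read and write GMT gene-set files
#'
#' GMT is tab-delimited: set name, description, then member genes. Reading
#' uppercases identifiers and drops duplicates within a set.
#'
#' @param path GMT file path.
#' @param collection named list of character vectors.
#' @param description description field written for every set.
#' @return `read_gmt` returns a named list of character vectors;
#'   `write_gmt` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) next
    out[[parts[1]]] <- unique(toupper(parts[-(1:2)]))
  }
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, description, collection[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a gene-set collection to a background universe
#'
#' Each list is intersected with the background (the analysed genes); lists
#' emptied by the restriction are dropped with a warning. Duplicate
#' identifiers collapse.
#'
#' @param collection named list of character vectors.
#' @param background character vector of analysed gene identifiers.
#' @return the restricted collection.
#' @export
restrict_to_background <- function(collection, background) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  out <- lapply(collection, function(g) intersect(unique(g), background))
  empty <- vapply(out, length, 1L) == 0
  if (any(empty))
    warning("dropping ", sum(empty), " list(s) with no background overlap: ",
            paste(names(out)[empty], collapse = ", "), call. = FALSE)
  out[!empty]
}

#' Hypergeometric enrichment of modules in gene lists
#'
#' For every (module, list) pair, tests whether the module contains more
#' list genes than expected from a uniform draw out of the background; the
#' raw p is the inclusive upper hypergeometric tail and the adjusted p is
#' Bonferroni over all (module, list) tests in the run. Module 0 is
#' excluded from testing.
#'
#' @param assignment named integer vector gene -> module label.
#' @param collection named list of gene sets, already restricted to the
#'   background (see [restrict_to_background()]).
#' @param background character vector of analysed genes.
#' @return data.frame with columns `module`, `list_name`, `module_size`,
#'   `list_size`, `background_size`, `overlap`, `p`, `adjP`, `significant`
#'   (adjP < 0.05).
#' @export
hypergeom_enrichment <- function(assignment, collection, background) {
  assignment <- assignment[names(assignment) %in% background]
  labs <- setdiff(sort(unique(assignment)), 0L)
  N <- length(background)
  if (any(vapply(labs, function(l) sum(assignment == l), 1L) > N))
    stop("background smaller than a module", call. = FALSE)
  rows <- list()
  for (l in labs) {
    members <- names(assignment)[assignment == l]
    for (nm in names(collection)) {
      gl <- intersect(collection[[nm]], background)
      x <- length(intersect(members, gl))
      rows[[length(rows) + 1L]] <- data.frame(
        module = l, list_name = nm, module_size = length(members),
        list_size = length(gl), background_size = N, overlap = x,
        p = hypergeom_tail_p(x, m = length(members), l = length(gl), N = N))
    }
  }
  if (length(rows) == 0)
    return(data.frame(module = integer(), list_name = character(),
                      module_size = integer(), list_size = integer(),
                      background_size = integer(), overlap = integer(),
                      p = numeric(), adjP = numeric(),
                      significant = logical()))
  res <- do.call(rbind, rows)
  res <- bonferroni(res, nrow(res))
  res$significant <- res$adjP < 0.05
  res
}

#' Bonferroni correction
#'
#' `adjP = min(1, p * n_tests)`.
#'
#' @param results data.frame with a `p` column.
#' @param n_tests number of tests in the family (at least `nrow(results)`).
#' @return `results` with an `adjP` column.
#' @export
bonferroni <- function(results, n_tests) {
  stopifnot(n_tests >= nrow(results))
  results$adjP <- pmin(1, results$p * n_tests)
  results
}

#' Bootstrap empirical-null overlap test
#'
#' Tests whether a module's overlap with a risk-gene list exceeds chance by
#' drawing `B` random gene sets of the module's size from the background
#' (without replacement) and recording each replicate's overlap with the
#' risk list. The empirical p-value is `max(r, 1) / B`, where `r` counts
#' replicates whose overlap reaches the observed one, giving the `1/B`
#' floor; the add-one convention `(r + 1) / (B + 1)` is available via
#' `convention = "add_one"`. The risk list is restricted to the background
#' before testing.
#'
#' @param module_genes character vector, the module's genes (subset of
#'   background).
#' @param risk_list character vector of risk genes.
#' @param background character vector of analysed genes.
#' @param B number of bootstrap replicates (default 10000).
#' @param seed integer seed; the null is fully reproducible from it.
#' @param convention `"floor"` (default, `max(r, 1) / B`) or `"add_one"`.
#' @param exclude optional gene (e.g. the gene of interest) removed from
#'   the module before testing.
#' @return list of class `bootstrap_overlap`: `observed` overlap, `B`,
#'   `null_overlaps` (length-B integer vector), `empirical_p`, `seed`.
#' @export
bootstrap_overlap <- function(module_genes, risk_list, background,
                              B = 10000, seed = 1L,
                              convention = c("floor", "add_one"),
                              exclude = NULL) {
  convention <- match.arg(convention)
  if (!is.null(exclude)) module_genes <- setdiff(module_genes, exclude)
  if (!all(module_genes %in% background))
    stop("module genes must be a subset of the background", call. = FALSE)
  if (length(module_genes) > length(background))
    stop("module larger than background", call. = FALSE)
  risk <- intersect(unique(risk_list), background)
  x_obs <- length(intersect(module_genes, risk))
  m <- length(module_genes)
  is_risk <- background %in% risk
  N <- length(background)
  set.seed(seed)
  null_overlaps <- vapply(seq_len(B), function(b)
    sum(is_risk[sample.int(N, m)]), 1L)
  r <- sum(null_overlaps >= x_obs)
  p <- if (convention == "floor") max(r, 1) / B else (r + 1) / (B + 1)
  structure(list(observed = x_obs, B = B, null_overlaps = null_overlaps,
                 empirical_p = p, seed = seed, convention = convention),
            class = "bootstrap_overlap")
}

#' @export
print.bootstrap_overlap <- function(x, ...) {
  cat("Bootstrap overlap test (", x$B, " replicates, seed ", x$seed, ")\n",
      "  observed overlap: ", x$observed, "\n",
      "  null overlap:     mean ", signif(mean(x$null_overlaps), 3),
      ", max ", max(x$null_overlaps), "\n",
      "  empirical p:      ", format(x$empirical_p), "\n", sep = "")
  invisible(x)
}
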