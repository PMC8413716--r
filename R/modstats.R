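# Module eigengenes, eigengene-trait correlations and cross-network module
# label matching.

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized member expression profiles, used as a one-number-per-sample
#' summary of the module. Member genes are standardized (mean 0, sd 1
#' across samples) before the PCA; the eigengene is scaled to unit variance
#' and its sign oriented so that it correlates positively with the module's
#' mean standardized expression. Module 0 (background) is excluded.
#'
#' @param expr genes x samples expression matrix.
#' @param assignment named integer vector gene -> module label.
#' @return list of class `eigengene_set`: per module (name `ME<label>`) a
#'   list with `eigengene` (named sample vector, unit variance) and
#'   `variance_explained` (leading eigenvalue share in `[0, 1]`).
#' @export
module_eigengenes <- function(expr, assignment) {
  assignment <- assignment[names(assignment) %in% rownames(expr)]
  labs <- setdiff(sort(unique(assignment)), 0L)
  out <- list()
  for (l in labs) {
    genes <- names(assignment)[assignment == l]
    if (length(genes) < 2)
      stop("module ", l, " has fewer than 2 genes in the matrix",
           call. = FALSE)
    x <- expr[genes, , drop = FALSE]
    xs <- t(scale(t(x)))                       # per-gene standardization
    if (anyNA(xs)) stop("constant gene in module ", l, call. = FALSE)
    sv <- svd(xs, nu = 0, nv = 1)
    me <- sv$v[, 1]
    ve <- sv$d[1]^2 / sum(sv$d^2)
    if (stats::cor(me, colMeans(xs)) < 0) me <- -me
    me <- me / stats::sd(me)
    names(me) <- colnames(expr)
    out[[paste0("ME", l)]] <- list(eigengene = me, variance_explained = ve)
  }
  structure(out, class = "eigengene_set")
}

#' Matrix view of an eigengene set
#'
#' @param mes an `eigengene_set`.
#' @return modules x samples numeric matrix of eigengene values.
#' @export
eigengene_matrix <- function(mes) {
  do.call(rbind, lapply(mes, `[[`, "eigengene"))
}

# Encode a sample trait as one or more numeric columns: numeric passthrough,
# two-level categorical -> 0/1, multi-level -> one indicator per level.
encode_trait <- function(x, name) {
  if (is.numeric(x)) return(stats::setNames(list(x), name))
  f <- factor(x)
  if (nlevels(f) < 2) return(NULL)                    # flagged by caller
  if (nlevels(f) == 2)
    return(stats::setNames(list(as.numeric(f) - 1), name))
  cols <- lapply(levels(f), function(lv) as.numeric(f == lv))
  stats::setNames(cols, paste0(name, "=", levels(f)))
}

#' Eigengene-trait correlations
#'
#' Pearson correlation of each module eigengene with each encoded sample
#' trait, with the exact two-sided p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Two-level categorical traits are encoded 0/1; multi-level traits (e.g.
#' brain region) get one indicator column per level. Constant traits are
#' excluded with a warning.
#'
#' @param mes an `eigengene_set` from [module_eigengenes()].
#' @param samples data.frame with `sample_id` and trait columns.
#' @return data.frame with columns `module`, `trait`, `r`, `p_value`.
#' @export
eigengene_trait_correlation <- function(mes, samples) {
  me_mat <- eigengene_matrix(mes)
  samples <- samples[match(colnames(me_mat), samples$sample_id), ,
                     drop = FALSE]
  trait_cols <- setdiff(names(samples), "sample_id")
  encoded <- list()
  for (tr in trait_cols) {
    enc <- encode_trait(samples[[tr]], tr)
    if (is.null(enc) ||
        any(vapply(enc, function(v) stats::sd(v) == 0, logical(1)))) {
      warning("trait '", tr, "' is constant; correlation undefined, ",
              "excluded", call. = FALSE)
      next
    }
    encoded <- c(encoded, enc)
  }
  n <- ncol(me_mat)
  rows <- list()
  for (m in rownames(me_mat)) for (tr in names(encoded)) {
    r <- stats::cor(me_mat[m, ], encoded[[tr]])
    p <- if (abs(r) >= 1) 0 else {
      t_stat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(t_stat), df = n - 2)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(module = m, trait = tr, r = r, p_value = p)
  }
  if (length(rows) == 0)
    return(data.frame(module = character(), trait = character(),
                      r = numeric(), p_value = numeric()))
  do.call(rbind, rows)
}

#' Match module labels across two networks
#'
#' Relabels the modules of `test` to the labels of the `reference` modules
#' they significantly overlap with, so that the "same" module carries the
#' same label across networks (e.g. across age intervals). For every
#' (test module, reference module) pair the hypergeometric upper-tail
#' overlap p-value is computed on the shared gene universe; pairs are then
#' matched greedily in ascending p order (ties broken by larger overlap,
#' then smaller reference label), each reference label used at most once,
#' and only when `p < p_threshold`. Unmatched test modules receive fresh
#' labels continuing after the reference's maximum. Module 0 stays 0.
#'
#' @param reference,test named integer module assignments on a shared gene
#'   universe.
#' @param p_threshold overlap significance threshold (default 0.05).
#' @return list: `assignment` (the relabelled test assignment), `pairs`
#'   (data.frame audit trail of all pairwise overlaps and p-values with the
#'   accepted matches flagged).
#' @export
match_labels <- function(reference, test, p_threshold = 0.05) {
  universe <- intersect(names(reference), names(test))
  if (length(universe) == 0) stop("disjoint gene universes", call. = FALSE)
  ref <- reference[universe]
  tst <- test[universe]
  ref_labs <- setdiff(sort(unique(ref)), 0L)
  tst_labs <- setdiff(sort(unique(tst)), 0L)
  N <- length(universe)
  pairs <- expand.grid(test_module = tst_labs, ref_module = ref_labs)
  if (nrow(pairs)) {
    pairs$overlap <- mapply(function(tm, rm)
      sum(tst == tm & ref == rm), pairs$test_module, pairs$ref_module)
    pairs$p <- mapply(function(tm, rm, x)
      hypergeom_tail_p(x, m = sum(tst == tm), l = sum(ref == rm), N = N),
      pairs$test_module, pairs$ref_module, pairs$overlap)
  } else {
    pairs$overlap <- integer()
    pairs$p <- numeric()
  }
  ord <- order(pairs$p, -pairs$overlap, pairs$ref_module)
  mapping <- stats::setNames(rep(NA_integer_, length(tst_labs)),
                             tst_labs)
  used_ref <- integer()
  pairs$matched <- FALSE
  for (i in ord) {
    tm <- pairs$test_module[i]; rm <- pairs$ref_module[i]
    if (pairs$p[i] >= p_threshold) break
    if (!is.na(mapping[as.character(tm)]) || rm %in% used_ref) next
    mapping[as.character(tm)] <- rm
    used_ref <- c(used_ref, rm)
    pairs$matched[i] <- TRUE
  }
  next_new <- if (length(ref_labs)) max(ref_labs) else 0L
  for (tm in tst_labs) {
    if (is.na(mapping[as.character(tm)])) {
      next_new <- next_new + 1L
      mapping[as.character(tm)] <- next_new
    }
  }
  out <- test
  pos <- out > 0L
  out[pos] <- mapping[as.character(test[pos])]
  list(assignment = out, pairs = pairs)
}
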