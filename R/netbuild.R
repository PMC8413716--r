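# Weighted coexpression network construction: Pearson correlation,
# soft-thresholded adjacency, scale-free topology fit, power selection and
# the topological overlap matrix (TOM).

#' Network construction configuration
#'
#' @param candidate_powers strictly increasing positive integers tried as
#'   soft-threshold exponents.
#' @param r2_target scale-free fit index the selected power must reach
#'   (default 0.85).
#' @param network_sign `"unsigned"` (adjacency `|r|^power`, default) or
#'   `"signed"` (`((1 + r) / 2)^power`).
#' @param n_bins number of equal-width connectivity bins for the scale-free
#'   fit (default 10).
#' @return a list of class `network_config`.
#' @export
network_config <- function(candidate_powers = 1:20, r2_target = 0.85,
                           network_sign = c("unsigned", "signed"),
                           n_bins = 10) {
  candidate_powers <- as.integer(candidate_powers)
  stopifnot(length(candidate_powers) > 0, all(candidate_powers >= 1),
            !is.unsorted(candidate_powers, strictly = TRUE),
            r2_target > 0, r2_target <= 1, n_bins >= 2)
  structure(list(candidate_powers = candidate_powers, r2_target = r2_target,
                 network_sign = match.arg(network_sign),
                 n_bins = as.integer(n_bins)),
            class = "network_config")
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlation of expression profiles across samples. Constant genes are an
#' error (their correlation is undefined) and are reported by name.
#'
#' @param expr genes x samples numeric matrix, at least 3 samples, no
#'   missing values.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(expr)) stop("missing values are not supported; filter upstream",
                        call. = FALSE)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  r <- stats::cor(t(expr))
  diag(r) <- 1
  r
}

#' Soft-thresholded adjacency
#'
#' Unsigned: `a_ij = |r_ij|^power`; signed: `a_ij = ((1 + r_ij) / 2)^power`.
#' The diagonal is forced to 1.
#'
#' @param cor_mat correlation matrix.
#' @param power soft-threshold exponent, `>= 1`.
#' @param sign `"unsigned"` or `"signed"`.
#' @return adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(cor_mat, power,
                             sign = c("unsigned", "signed")) {
  stopifnot(power >= 1)
  sign <- match.arg(sign)
  a <- if (sign == "unsigned") abs(cor_mat)^power
       else ((1 + cor_mat) / 2)^power
  diag(a) <- 1
  a
}

#' Per-gene connectivity
#'
#' `k_i` is the sum of the adjacency of gene i to all other genes.
#'
#' @param adj adjacency matrix.
#' @return named numeric vector of connectivities.
#' @export
connectivity <- function(adj) {
  rowSums(adj) - diag(adj)
}

#' Scale-free topology fit
#'
#' Bins connectivity into `n_bins` equal-width bins, computes per nonempty
#' bin the mean connectivity and the frequency p(k), and fits the simple
#' linear regression of log10 p(k) on log10 mean k. The fit index is the
#' squared correlation of the two; a scale-free network gives a straight,
#' negatively sloped line.
#'
#' @param k connectivity vector (needs at least `n_bins` distinct positive
#'   values).
#' @param n_bins number of equal-width bins.
#' @return list of class `scale_free_fit` with `r2`, `slope`,
#'   `mean_connectivity` and the binned table.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) stop("scale-free fit undefined: connectivity ",
                                  "has fewer than 2 distinct values",
                                  call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  tab <- tapply(k, bin, length)
  nonempty <- !is.na(tab) & tab > 0
  mean_k <- tapply(k, bin, mean)[nonempty]
  p_k <- tab[nonempty] / length(k)
  x <- log10(mean_k)
  y <- log10(p_k)
  if (length(x) < 2) stop("scale-free fit undefined: all connectivities ",
                          "fall in one bin", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- stats::cor(x, y)^2
  structure(list(r2 = unname(r2), slope = unname(fit$coefficients[2]),
                 mean_connectivity = mean(k),
                 bins = data.frame(mean_k = as.numeric(mean_k),
                                   p_k = as.numeric(p_k))),
            class = "scale_free_fit")
}

#' Select the soft-threshold power by scale-free topology
#'
#' Tries each candidate power on the same correlation matrix and returns the
#' smallest power whose scale-free fit index reaches `r2_target`. If none
#' qualifies, the power with the maximal fit index is returned and flagged.
#'
#' @param expr genes x samples expression matrix.
#' @param cfg a [network_config()].
#' @param cor_mat optional precomputed correlation matrix (skips
#'   recomputation).
#' @return list of class `power_pick`: `power` (integer), `fit` (the
#'   [scale_free_fit()] at the chosen power), `table` (data.frame of power,
#'   r2, slope, mean_k), `reached_target` (logical).
#' @export
pick_power <- function(expr, cfg = network_config(), cor_mat = NULL) {
  if (is.null(cor_mat)) cor_mat <- correlation_matrix(expr)
  rows <- vector("list", length(cfg$candidate_powers))
  fits <- vector("list", length(cfg$candidate_powers))
  chosen <- NA_integer_
  for (i in seq_along(cfg$candidate_powers)) {
    p <- cfg$candidate_powers[i]
    adj <- adjacency_matrix(cor_mat, p, cfg$network_sign)
    f <- scale_free_fit(connectivity(adj), cfg$n_bins)
    fits[[i]] <- f
    rows[[i]] <- data.frame(power = p, r2 = f$r2, slope = f$slope,
                            mean_k = f$mean_connectivity)
    if (is.na(chosen) && f$r2 >= cfg$r2_target) chosen <- i
  }
  tab <- do.call(rbind, rows)
  reached <- !is.na(chosen)
  if (!reached) {
    chosen <- which.max(tab$r2)
    warning("no candidate power reached r2 target ", cfg$r2_target,
            "; using power ", tab$power[chosen], " (r2 = ",
            signif(tab$r2[chosen], 3), ")", call. = FALSE)
  }
  structure(list(power = tab$power[chosen], fit = fits[[chosen]],
                 table = tab, reached_target = reached),
            class = "power_pick")
}

#' Topological overlap matrix
#'
#' For an adjacency `a` with connectivities `k`,
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' where `L_ij = sum_{u != i,j} a_iu a_uj` counts shared neighbours; the
#' diagonal is 1. Two genes overlap strongly when they are directly
#' connected and share the same neighbourhood.
#'
#' @param adj adjacency matrix in `[0, 1]` with unit diagonal.
#' @return TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  k <- connectivity(adj)
  # A %*% A includes the i and j terms; remove them to get L
  L <- adj %*% adj - adj * (matrix(diag(adj), nrow(adj), ncol(adj)) +
                            matrix(diag(adj), nrow(adj), ncol(adj),
                                   byrow = TRUE))
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (L + adj) / denom
  diag(tom) <- 1
  tom
}
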