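# The per-dataset model fit: expression matrix in, coexpression network +
# modules + eigengenes out, as a classed S3 object.

#' Fit a weighted gene coexpression network
#'
#' The central fitting function. Given a genes x samples log2 expression
#' matrix it (1) selects the soft-threshold power as the smallest candidate
#' whose connectivity distribution fits scale-free topology at the target
#' R-squared, (2) forms the soft-thresholded adjacency and the topological
#' overlap matrix (TOM), (3) clusters `1 - TOM` with average linkage and
#' (4) cuts the dendrogram adaptively into modules, relabelled by
#' decreasing size (module 0 = unassigned background), and (5) summarises
#' each module by its eigengene (first principal component).
#'
#' @param expr genes x samples numeric matrix (log2 scale, no missing
#'   values, no constant genes).
#' @param network a [network_config()].
#' @param treecut a [treecut_config()].
#' @param power optional fixed soft-threshold power; if `NULL` (default)
#'   the power is selected from `network$candidate_powers`.
#' @param keep_tom keep the TOM matrix in the returned object (default
#'   `FALSE`; it is quadratic in the number of genes).
#' @return an object of class `coexnet` with components `power`,
#'   `power_pick`, `modules` (named gene -> label vector), `dendrogram`
#'   (hclust), `eigengenes` (see [module_eigengenes()]), `n_genes`,
#'   `n_samples`, and optionally `tom`.
#' @examples
#' d <- generate_dataset(synth_config(300, 60, c(120, 100), seed = 1))
#' fit <- coexnet(d$expr)
#' fit
#' table(modules(fit))
#' @export
coexnet <- function(expr, network = network_config(),
                    treecut = treecut_config(), power = NULL,
                    keep_tom = FALSE) {
  cor_mat <- correlation_matrix(expr)
  if (is.null(power)) {
    pp <- pick_power(expr, network, cor_mat = cor_mat)
    power <- pp$power
  } else {
    adj1 <- adjacency_matrix(cor_mat, power, network$network_sign)
    f <- scale_free_fit(connectivity(adj1), network$n_bins)
    pp <- structure(list(power = as.integer(power), fit = f,
                         table = data.frame(power = as.integer(power),
                                            r2 = f$r2, slope = f$slope,
                                            mean_k = f$mean_connectivity),
                         reached_target = f$r2 >= network$r2_target),
                    class = "power_pick")
  }
  adj <- adjacency_matrix(cor_mat, power, network$network_sign)
  tom <- tom_similarity(adj)
  hc <- cluster_tree(1 - tom)
  mods <- cut_tree_dynamic(hc, treecut)
  if (treecut$kme_reassign && any(mods > 0))
    mods <- assign_by_kme(expr, mods, treecut$kme_threshold)
  mes <- if (any(mods > 0)) module_eigengenes(expr, mods)
         else structure(list(), class = "eigengene_set")
  structure(list(power = as.integer(power), power_pick = pp,
                 modules = mods, dendrogram = hc, eigengenes = mes,
                 network_config = network, treecut_config = treecut,
                 n_genes = nrow(expr), n_samples = ncol(expr),
                 tom = if (keep_tom) tom else NULL),
            class = "coexnet")
}

#' Module assignment of a fitted network
#'
#' @param object a `coexnet` fit.
#' @return named integer vector gene -> module label (0 = background).
#' @export
modules <- function(object) UseMethod("modules")

#' @export
modules.coexnet <- function(object) object$modules

#' @export
print.coexnet <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$modules), 0L))
  cat("Weighted gene coexpression network\n",
      "  genes: ", x$n_genes, ", samples: ", x$n_samples, "\n",
      "  soft-threshold power: ", x$power,
      " (scale-free R2 = ", signif(x$power_pick$fit$r2, 3),
      if (!x$power_pick$reached_target) ", target not reached" else "",
      ")\n",
      "  modules: ", n_mod, " (+ background of ",
      sum(x$modules == 0L), " genes)\n", sep = "")
  invisible(x)
}

#' @export
summary.coexnet <- function(object, ...) {
  labs <- setdiff(sort(unique(object$modules)), 0L)
  tab <- data.frame(
    module = labs,
    color = module_colors(labs),
    size = vapply(labs, function(l) sum(object$modules == l), 1L),
    variance_explained = vapply(labs, function(l) {
      me <- object$eigengenes[[paste0("ME", l)]]
      if (is.null(me)) NA_real_ else me$variance_explained
    }, 1.0))
  structure(list(fit = object, modules = tab,
                 power_table = object$power_pick$table),
            class = "summary.coexnet")
}

#' @export
print.summary.coexnet <- function(x, ...) {
  print(x$fit)
  cat("\nModules (by decreasing size):\n")
  print(x$modules, row.names = FALSE)
  invisible(x)
}

#' @export
coef.coexnet <- function(object, ...) eigengene_matrix(object$eigengenes)

#' Plot a fitted coexpression network
#'
#' Draws the TOM dendrogram with a module-colour bar underneath (the usual
#' presentation of a coexpression network), or the scale-free fit index
#' against candidate powers.
#'
#' @param x a `coexnet` fit.
#' @param which `"dendrogram"` or `"power"`.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.coexnet <- function(x, which = c("dendrogram", "power"), ...) {
  which <- match.arg(which)
  if (which == "power") {
    tab <- x$power_pick$table
    graphics::plot(tab$power, tab$r2, type = "b", xlab = "soft power",
                   ylab = "scale-free fit R2", ...)
    graphics::abline(h = x$network_config$r2_target, lty = 2)
  } else {
    oldpar <- graphics::par(mar = c(0.5, 4, 2, 1), mfrow = c(2, 1))
    on.exit(graphics::par(oldpar))
    graphics::plot(x$dendrogram, labels = FALSE, hang = -1,
                   main = "TOM dissimilarity clustering", xlab = "",
                   sub = "", ...)
    cols <- module_colors(x$modules[x$dendrogram$labels[x$dendrogram$order]])
    graphics::par(mar = c(2, 4, 0.5, 1))
    graphics::image(matrix(seq_along(cols), ncol = 1),
                    col = ifelse(cols == "grey", "grey80", cols),
                    axes = FALSE)
  }
  invisible(x)
}
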