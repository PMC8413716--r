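# Module detection: average-linkage clustering of TOM dissimilarity and an
# adaptive (dynamic) branch cut of the dendrogram.
#
# The cut proceeds in two stages. A static cut at `cut_height` yields
# candidate branches; each branch is then examined recursively and split
# into its two sub-branches whenever both children (i) are large enough,
# (ii) have a tight core (the mean of the lowest merge heights in the
# child, the "core scatter", below a deep-split-dependent threshold) and
# (iii) hang well below the height at which they merge (the "gap").
# Clusters smaller than the minimum module size dissolve into the
# background module 0, and labels are reassigned by decreasing size.

#' Tree-cut configuration
#'
#' @param deep_split integer 0-4; split sensitivity. Higher values tolerate
#'   looser branch cores, producing more, smaller modules. Internally
#'   `deep_split` maps linearly to a maximum core scatter from 0.64 (0) to
#'   0.98 (4), with the minimum gap set to `0.75 * (1 - max core scatter)`;
#'   both are expressed on a scale normalised between the 5th percentile of
#'   merge heights and `cut_height`.
#' @param cut_height maximum dendrogram height at which branches are cut
#'   (default 0.99 on the 1 - TOM scale).
#' @param min_module_size smallest allowed module (default 27); smaller
#'   clusters are dissolved into module 0.
#' @param merge_similar reserved flag for eigengene-based module merging;
#'   off by default and not performed.
#' @param kme_reassign if `TRUE` (default) a second stage assigns genes
#'   left in module 0 by the branch cut to the module whose eigengene they
#'   correlate with most strongly, provided `|kME| >= kme_threshold`; see
#'   [assign_by_kme()]. Distance-based (PAM-like) reassignment is not
#'   performed.
#' @param kme_threshold minimum absolute eigengene correlation (module
#'   membership) for the reassignment stage (default 0.5, the conventional
#'   cutoff for moderate module membership).
#' @return a list of class `treecut_config`.
#' @export
treecut_config <- function(deep_split = 1, cut_height = 0.99,
                           min_module_size = 27, merge_similar = FALSE,
                           kme_reassign = TRUE, kme_threshold = 0.5) {
  stopifnot(deep_split %in% 0:4, cut_height > 0, cut_height <= 1,
            min_module_size >= 1, kme_threshold > 0, kme_threshold <= 1)
  max_core_scatter <- 0.64 + (0.98 - 0.64) * deep_split / 4
  structure(list(deep_split = as.integer(deep_split),
                 cut_height = cut_height,
                 min_module_size = as.integer(min_module_size),
                 merge_similar = merge_similar,
                 kme_reassign = kme_reassign,
                 kme_threshold = kme_threshold,
                 max_core_scatter = max_core_scatter,
                 min_gap = 0.75 * (1 - max_core_scatter)),
            class = "treecut_config")
}

#' Assign background genes to modules by eigengene membership
#'
#' The branch cut labels only the tight cores of modules; genes whose
#' branch attaches too high end up in module 0 even when they clearly
#' follow a module's expression profile. This stage computes each module's
#' eigengene from the core assignment and moves a background gene into the
#' module with which its module membership `kME = cor(gene, eigengene)` is
#' largest in absolute value, provided `|kME| >= threshold`. Core labels
#' are never changed; labels are re-ordered by size afterwards.
#'
#' @param expr genes x samples expression matrix.
#' @param assignment named integer vector gene -> module label from the
#'   branch cut.
#' @param threshold minimum `|kME|` for assignment.
#' @return the augmented assignment.
#' @export
assign_by_kme <- function(expr, assignment, threshold = 0.5) {
  labs <- setdiff(sort(unique(assignment)), 0L)
  un <- names(assignment)[assignment == 0L]
  if (length(labs) == 0 || length(un) == 0) return(assignment)
  mes <- module_eigengenes(expr, assignment)
  me_mat <- eigengene_matrix(mes)            # modules x samples
  kme <- stats::cor(t(expr[un, , drop = FALSE]), t(me_mat))
  best <- apply(abs(kme), 1, which.max)
  best_val <- abs(kme)[cbind(seq_along(best), best)]
  hit <- best_val >= threshold
  out <- assignment
  out[un[hit]] <- labs[best[hit]]
  relabel_by_size(out)
}

#' Average-linkage clustering of a TOM dissimilarity matrix
#'
#' @param diss symmetric dissimilarity matrix (typically `1 - TOM`) with
#'   zero diagonal and values in `[0, 1]`.
#' @return an [stats::hclust] object.
#' @export
cluster_tree <- function(diss) {
  if (!isSymmetric(unname(diss), tol = 1e-10))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  stats::hclust(stats::as.dist(diss), method = "average")
}

# Per-node bookkeeping for the merge matrix of an hclust object:
# leaves(node) and the merge heights inside each subtree.
subtree_info <- function(hc) {
  n <- length(hc$order)
  n_nodes <- nrow(hc$merge)
  leaves <- vector("list", n_nodes)
  heights <- vector("list", n_nodes)   # heights of merges within subtree
  for (v in seq_len(n_nodes)) {
    ch <- hc$merge[v, ]
    lv <- hv <- NULL
    for (c in ch) {
      if (c < 0) lv <- c(lv, -c)
      else { lv <- c(lv, leaves[[c]]); hv <- c(hv, heights[[c]]) }
    }
    leaves[[v]] <- lv
    heights[[v]] <- c(hv, hc$height[v])
  }
  list(leaves = leaves, heights = heights)
}

# Mean of the lowest merge heights in a subtree: the tightness of the
# cluster core (first `core_size - 1` merges).
core_scatter <- function(subtree_heights, core_size) {
  m <- min(core_size - 1L, length(subtree_heights))
  if (m < 1) return(0)
  mean(sort(subtree_heights, partial = m)[seq_len(m)])
}

#' Adaptive branch cut of a dendrogram into modules
#'
#' Implements the two-stage dynamic cut described in [treecut_config()]:
#' static cut at `cut_height`, recursive sub-branch splitting driven by the
#' core-scatter and gap criteria, dissolution of undersized clusters into
#' module 0, and size-ordered relabelling (1 = largest).
#'
#' @param hc an [stats::hclust] object (average linkage of `1 - TOM`).
#' @param cfg a [treecut_config()].
#' @return named integer vector gene -> module label; 0 is background.
#' @examples
#' d <- generate_dataset(synth_config(300, 60, c(120, 100), seed = 1))
#' net <- correlation_matrix(d$expr)
#' tom <- tom_similarity(adjacency_matrix(net, 6))
#' labels <- cut_tree_dynamic(cluster_tree(1 - tom))
#' table(labels)
#' @export
cut_tree_dynamic <- function(hc, cfg = treecut_config()) {
  if (cfg$cut_height <= 0 || cfg$cut_height > 1)
    stop("cut_height must be in (0, 1]", call. = FALSE)
  n <- length(hc$order)
  labels_out <- rep.int(0L, n)
  gene_ids <- if (is.null(hc$labels)) as.character(seq_len(n)) else hc$labels

  info <- subtree_info(hc)
  # the cut height and the deep-split thresholds are interpreted relative
  # to the spread of merge heights (between their 5th percentile and their
  # maximum), so the cut adapts to the compression of the dissimilarity
  # scale that strong soft-thresholding produces
  base <- stats::quantile(hc$height, 0.05, names = FALSE)
  h_cut <- base + cfg$cut_height * (max(hc$height) - base)
  abs_core_scatter <- base + cfg$max_core_scatter * (h_cut - base)
  abs_gap <- cfg$min_gap * (h_cut - base)

  # static cut: maximal nodes entirely below the cut
  below <- hc$height <= h_cut
  parent <- integer(nrow(hc$merge))          # parent node of each node
  for (v in seq_len(nrow(hc$merge)))
    for (c in hc$merge[v, ]) if (c > 0) parent[c] <- v
  root_nodes <- which(below & (parent == 0 | !below[pmax(parent, 1L)]))

  split_branch <- function(v) {
    # returns a list of integer leaf vectors (clusters) for subtree v
    size <- length(info$leaves[[v]])
    if (size < 2L * cfg$min_module_size) return(list(info$leaves[[v]]))
    ch <- hc$merge[v, ]
    ch_size <- ifelse(ch < 0, 1L,
                      vapply(pmax(ch, 1L), function(c)
                        length(info$leaves[[c]]), 1L))
    if (any(ch < 0) || any(ch_size < cfg$min_module_size))
      return(list(info$leaves[[v]]))
    h <- hc$height[v]
    ok <- vapply(ch, function(c) {
      gap <- h - hc$height[c]
      scat <- core_scatter(info$heights[[c]], cfg$min_module_size)
      gap >= abs_gap && scat <= abs_core_scatter
    }, logical(1))
    if (all(ok)) c(split_branch(ch[1]), split_branch(ch[2]))
    else list(info$leaves[[v]])
  }

  next_label <- 0L
  for (v in root_nodes) {
    for (cl in split_branch(v)) {
      if (length(cl) >= cfg$min_module_size) {
        next_label <- next_label + 1L
        labels_out[cl] <- next_label
      }
    }
  }
  names(labels_out) <- gene_ids
  relabel_by_size(labels_out)
}

#' Relabel modules by decreasing size
#'
#' Module 1 becomes the largest; ties are broken by the smallest member
#' gene identifier (lexicographic). Module 0 is unchanged.
#'
#' @param assignment named integer vector gene -> module label.
#' @return relabelled assignment with contiguous labels 1..M.
#' @export
relabel_by_size <- function(assignment) {
  labs <- setdiff(sort(unique(assignment)), 0L)
  if (length(labs) == 0) return(assignment)
  sizes <- vapply(labs, function(l) sum(assignment == l), 1L)
  first_gene <- vapply(labs, function(l)
    min(names(assignment)[assignment == l]), "")
  ord <- labs[order(-sizes, first_gene)]
  out <- assignment
  for (i in seq_along(ord)) out[assignment == ord[i]] <- i
  out
}

#' Conventional module colour names
#'
#' Maps size-ordered module labels to the conventional palette used for
#' coexpression modules (0 = grey, 1 = turquoise, 2 = blue, 3 = brown, ...),
#' so modules can be reported by colour.
#'
#' @param labels integer module labels.
#' @return character vector of colour names (labels beyond the palette fall
#'   back to `module<label>`).
#' @export
module_colors <- function(labels) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue", "darkred",
               "darkgreen", "darkturquoise", "darkgrey", "orange",
               "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
  out <- ifelse(labels == 0, "grey",
                ifelse(labels <= length(palette), palette[pmax(labels, 1L)],
                       paste0("module", labels)))
  out[is.na(out)] <- NA_character_
  out
}
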