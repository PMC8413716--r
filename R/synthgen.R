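# Synthetic expression data with planted coexpression modules.
#
# The generator follows a latent-factor model: each planted module m has a
# latent profile f_m (iid standard normal across samples), and a member gene g
# has expression  x_gs = lambda_g * f_m(s) + eps_gs  with a positive loading
# lambda_g ~ U(loading_range) and noise eps ~ N(0, noise_sd^2). Background
# genes are unit-variance Gaussian noise. Everything is shifted by +8 so the
# values look like plausible log2 microarray intensities.

#' Configuration for the synthetic data generator
#'
#' Collects and validates all knobs of the planted-module factor model.
#'
#' @param n_genes total number of genes (planted modules plus background).
#' @param n_samples number of samples (columns).
#' @param module_sizes integer vector; size of each planted module. Must sum
#'   to `n_genes * (1 - background_fraction)` (the remainder is background).
#' @param noise_sd standard deviation of the additive gene-level noise.
#' @param loading_range length-2 numeric in (0, 1]; loadings are drawn
#'   uniformly from this interval. Loadings are positive so that planted
#'   modules are coherent under an unsigned network.
#' @param background_fraction fraction of `n_genes` that are pure-noise
#'   background genes.
#' @param trait_spec optional list of traits; each element is
#'   `list(name =, module =, strength =)` giving a sample trait correlated
#'   with the latent profile of the stated module at the stated strength.
#' @param marker_spec optional named list mapping module index (as character,
#'   e.g. `"1"`) to a marker-list size; used by [generate_marker_collection()].
#' @param risk_spec optional `list(module =, size =, fraction =)`; used by
#'   [generate_risk_list()]. `fraction` of the list is drawn from the stated
#'   module, the rest uniformly from all other genes.
#' @param low_expr_fraction fraction of background genes written at a low
#'   mean intensity (around 5 instead of 8) so that the minimum-expression
#'   filter has something to remove.
#' @param seed integer seed; all randomness flows from it through
#'   per-component sub-streams, so identical configs give bit-identical data.
#'
#' @return an object of class `synth_config` (a validated list).
#' @seealso [generate_dataset()]
#' @export
synth_config <- function(n_genes, n_samples, module_sizes,
                         noise_sd = 1,
                         loading_range = c(0.7, 0.9),
                         background_fraction = NULL,
                         trait_spec = list(),
                         marker_spec = list(),
                         risk_spec = NULL,
                         low_expr_fraction = 0,
                         seed = 1L) {
  module_sizes <- as.integer(module_sizes)
  if (any(module_sizes < 1L))
    stop("every module size must be >= 1", call. = FALSE)
  n_module_genes <- sum(module_sizes)
  if (is.null(background_fraction))
    background_fraction <- 1 - n_module_genes / n_genes
  n_background <- n_genes - n_module_genes
  if (n_background < 0 ||
      abs(n_background - round(n_genes * background_fraction)) > 0.5)
    stop("inconsistent sizes: sum(module_sizes) + background genes must ",
         "equal n_genes (got ", n_module_genes, " module genes, ",
         "background_fraction ", signif(background_fraction, 3),
         ", n_genes ", n_genes, ")", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(length(loading_range) == 2, loading_range[1] <= loading_range[2],
            loading_range[1] > 0, loading_range[2] <= 1,
            low_expr_fraction >= 0, low_expr_fraction < 1)
  for (tr in trait_spec)
    stopifnot(!is.null(tr$name), tr$module >= 1,
              tr$module <= length(module_sizes), abs(tr$strength) <= 1)
  if (!is.null(risk_spec))
    stopifnot(risk_spec$module >= 1, risk_spec$module <= length(module_sizes),
              risk_spec$size >= 0, risk_spec$fraction >= 0,
              risk_spec$fraction <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 module_sizes = module_sizes,
                 n_background = as.integer(n_background),
                 noise_sd = noise_sd,
                 loading_range = loading_range,
                 background_fraction = background_fraction,
                 trait_spec = trait_spec,
                 marker_spec = marker_spec,
                 risk_spec = risk_spec,
                 low_expr_fraction = low_expr_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Derive a reproducible sub-stream seed for a named generator component.
# Offsets keep the seeds distinct and inside 32-bit integer range.
sub_seed <- function(seed, component) {
  offsets <- c(latent = 101L, loadings = 211L, noise = 307L,
               background = 401L, traits = 503L, markers = 601L,
               risk = 701L, lowexpr = 809L)
  (as.integer(seed) * 1009L + offsets[[component]]) %% 2147483647L
}

#' Generate a synthetic expression dataset with known module structure
#'
#' Draws a genes-by-samples log2-scale expression matrix from the planted
#' factor model described in [synth_config()], together with a sample table
#' carrying any configured traits and the ground truth needed to score
#' downstream module detection.
#'
#' @param config a [synth_config()] object.
#' @return a list with components
#'   \describe{
#'     \item{expr}{numeric matrix, genes x samples, rownames `G0001...`,
#'       colnames `S001...`; values centred around 8 (log2-intensity scale).}
#'     \item{samples}{data.frame with `sample_id` plus one column per trait.}
#'     \item{truth}{list: `assignment` (named integer vector, 0 = background),
#'       `latent_profiles` (modules x samples matrix), `marker_lists`,
#'       `risk_list` (filled by the respective generators, else `NULL`).}
#'   }
#' @examples
#' cfg <- synth_config(120, 30, module_sizes = c(50, 40), seed = 7)
#' d <- generate_dataset(cfg)
#' table(d$truth$assignment)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  M <- length(config$module_sizes)
  S <- config$n_samples
  G <- config$n_genes

  gene_ids <- sprintf("G%0*d", max(4, nchar(G)), seq_len(G))
  sample_ids <- sprintf("S%0*d", max(3, nchar(S)), seq_len(S))

  set.seed(sub_seed(config$seed, "latent"))
  latent <- matrix(stats::rnorm(M * S), nrow = M, ncol = S,
                   dimnames = list(paste0("M", seq_len(M)), sample_ids))

  assignment <- rep.int(seq_len(M), config$module_sizes)
  assignment <- c(assignment, rep.int(0L, config$n_background))
  names(assignment) <- gene_ids

  set.seed(sub_seed(config$seed, "loadings"))
  lambda <- stats::runif(sum(config$module_sizes),
                         config$loading_range[1], config$loading_range[2])

  expr <- matrix(0, nrow = G, ncol = S,
                 dimnames = list(gene_ids, sample_ids))
  in_mod <- assignment > 0L
  expr[in_mod, ] <- lambda * latent[assignment[in_mod], , drop = FALSE]

  set.seed(sub_seed(config$seed, "noise"))
  if (config$noise_sd > 0)
    expr[in_mod, ] <- expr[in_mod, ] +
      matrix(stats::rnorm(sum(in_mod) * S, sd = config$noise_sd),
             nrow = sum(in_mod))

  set.seed(sub_seed(config$seed, "background"))
  if (config$n_background > 0)
    expr[!in_mod, ] <- matrix(stats::rnorm(config$n_background * S),
                              nrow = config$n_background)

  expr <- expr + 8

  # optionally push a slice of background genes below the expression filter
  if (config$low_expr_fraction > 0 && config$n_background > 0) {
    set.seed(sub_seed(config$seed, "lowexpr"))
    bg_ids <- gene_ids[!in_mod]
    n_low <- round(config$low_expr_fraction * length(bg_ids))
    low <- sample(bg_ids, n_low)
    expr[low, ] <- expr[low, ] - 3
  }

  samples <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (length(config$trait_spec)) {
    set.seed(sub_seed(config$seed, "traits"))
    for (tr in config$trait_spec) {
      z <- stats::rnorm(S)
      rho <- tr$strength
      samples[[tr$name]] <- rho * latent[tr$module, ] +
        sqrt(1 - rho^2) * z
    }
  }

  truth <- list(assignment = assignment, latent_profiles = latent,
                marker_lists = NULL, risk_list = NULL)
  list(expr = expr, samples = samples, truth = truth)
}

#' Draw marker gene lists from planted modules
#'
#' Emulates curated cell-type marker collections: each configured list is a
#' uniform random subset of one planted module's true member genes.
#'
#' @param truth the `truth` component returned by [generate_dataset()].
#' @param config the [synth_config()] used to generate the data; its
#'   `marker_spec` maps module index (character) to list size.
#' @return a named list of character vectors (a gene-set collection); names
#'   are `markers_M<module>`.
#' @export
generate_marker_collection <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  out <- list()
  set.seed(sub_seed(config$seed, "markers"))
  for (mod_chr in names(config$marker_spec)) {
    m <- as.integer(mod_chr)
    size <- config$marker_spec[[mod_chr]]
    members <- names(truth$assignment)[truth$assignment == m]
    if (length(members) == 0)
      stop("marker_spec refers to module ", m, " which has no genes",
           call. = FALSE)
    if (size > length(members))
      stop("requested marker list size ", size, " exceeds module ", m,
           " size ", length(members), call. = FALSE)
    out[[paste0("markers_M", m)]] <- sort(sample(members, size))
  }
  out
}

#' Draw a risk-gene list enriched in one planted module
#'
#' A configured fraction of the list comes from the enriched module; the rest
#' is drawn uniformly from all genes not already picked (so a fraction of 0
#' gives an unbiased uniform list). No duplicates.
#'
#' @inheritParams generate_marker_collection
#' @return character vector of gene identifiers.
#' @export
generate_risk_list <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  rs <- config$risk_spec
  if (is.null(rs)) stop("config has no risk_spec", call. = FALSE)
  universe <- names(truth$assignment)
  if (rs$size > length(universe))
    stop("risk list size exceeds gene universe", call. = FALSE)
  members <- universe[truth$assignment == rs$module]
  n_in <- min(round(rs$fraction * rs$size), length(members))
  set.seed(sub_seed(config$seed, "risk"))
  from_module <- if (n_in > 0) sample(members, n_in) else character()
  pool <- setdiff(universe, from_module)
  from_rest <- if (rs$size - n_in > 0) sample(pool, rs$size - n_in)
               else character()
  sort(c(from_module, from_rest))
}

#' Write a synthetic dataset to plain-text files
#'
#' Persists the expression matrix and sample table as TSV, marker lists as
#' GMT, the risk list as one gene per line, and the true assignment as a
#' two-column TSV.
#'
#' @param dataset list returned by [generate_dataset()] (optionally with
#'   `truth$marker_lists` / `truth$risk_list` filled in).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(dataset$expr, file.path(dir, "expression.tsv"))
  utils::write.table(dataset$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  utils::write.table(
    data.frame(gene_id = names(truth$assignment),
               module = unname(truth$assignment)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(truth$marker_lists))
    write_gmt(truth$marker_lists, file.path(dir, "markers.gmt"))
  if (!is.null(truth$risk_list))
    writeLines(truth$risk_list, file.path(dir, "risk_list.txt"))
  invisible(dir)
}

#' Read / write an expression matrix as TSV
#'
#' Genes are rows (first column `gene_id`), the header carries sample IDs.
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @return `read_expression_tsv` returns a numeric matrix;
#'   `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
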