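# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Small planted-module dataset for fast end-to-end checks.
small_dataset <- function(seed = 1, n_samples = 60,
                          module_sizes = c(120, 100, 80),
                          noise_sd = 1, ...) {
  cfg <- synth_config(n_genes = sum(module_sizes) + 100,
                      n_samples = n_samples, module_sizes = module_sizes,
                      loading_range = c(0.7, 0.9), noise_sd = noise_sd,
                      seed = seed, ...)
  list(cfg = cfg, data = generate_dataset(cfg))
}

# The standard fixture: 2,000 genes, 100 samples, five planted modules.
standard_fixture <- function(seed = 42) {
  cfg <- synth_config(2000, 100, module_sizes = c(300, 250, 200, 150, 100),
                      loading_range = c(0.7, 0.9), noise_sd = 1, seed = seed)
  generate_dataset(cfg)
}

# Random valid unsigned adjacency matrix (symmetric, [0,1], unit diagonal).
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Naive triple-loop TOM, the independent oracle for tom_similarity().
tom_oracle <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj) - diag(adj)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + adj[i, u] * adj[u, j]
    out[i, j] <- (L + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  out
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric overlap
# p-value: enumerate every m-subset of a population of size N containing l
# marked elements and count those overlapping the marks in at least x.
hypergeom_enum_oracle <- function(x, m, l, N) {
  draws <- utils::combn(N, m)
  marked <- seq_len(l)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= x)
  sum(hits) / ncol(draws)
}

# Planted-module ARI on module genes only (background excluded), via the
# independent mclust implementation.
planted_ari <- function(truth, found) {
  in_mod <- truth > 0
  mclust::adjustedRandIndex(truth[in_mod], found[names(truth)[in_mod]])
}
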