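make_me_set <- function(vectors, sample_ids) {
  out <- lapply(vectors, function(v) {
    names(v) <- sample_ids
    list(eigengene = v / sd(v), variance_explained = 1)
  })
  structure(out, class = "eigengene_set")
}

test_that("a rank-1 module gives variance_explained 1 and |cor| 1", {
  s <- paste0("S", 1:20)
  base <- rnorm(20)
  expr <- rbind(g1 = 2 * base + 1, g2 = -0.5 * base + 3, g3 = base)
  colnames(expr) <- s
  mes <- module_eigengenes(expr, c(g1 = 1L, g2 = 1L, g3 = 1L))
  expect_equal(mes$ME1$variance_explained, 1, tolerance = 1e-12)
  me <- mes$ME1$eigengene
  expect_equal(sd(me), 1, tolerance = 1e-12)
  for (g in rownames(expr))
    expect_equal(abs(cor(me, expr[g, ])), 1, tolerance = 1e-10)
  # orientation: positive correlation with the mean standardized profile
  expect_gt(cor(me, colMeans(t(scale(t(expr))))), 0)
})

test_that("eigengene is invariant to jointly flipping all member genes", {
  set.seed(5)
  expr <- matrix(rnorm(80), 4, 20,
                 dimnames = list(paste0("g", 1:4), paste0("S", 1:20)))
  a <- setNames(rep(1L, 4), rownames(expr))
  me1 <- module_eigengenes(expr, a)$ME1$eigengene
  me2 <- module_eigengenes(-expr, a)$ME1$eigengene
  expect_equal(abs(cor(me1, me2)), 1, tolerance = 1e-10)
})

test_that("two orthogonal equal-variance patterns share the variance equally", {
  p1 <- c(1, 1, -1, -1)
  p2 <- c(1, -1, 1, -1)
  expr <- rbind(a = p1, b = p1, c = p2, d = p2)
  colnames(expr) <- paste0("S", 1:4)
  mes <- module_eigengenes(expr, setNames(rep(1L, 4), rownames(expr)))
  expect_equal(mes$ME1$variance_explained, 0.5, tolerance = 1e-12)
})

test_that("variance explained matches the full spectral decomposition", {
  for (s in 1:5) {
    set.seed(s)
    expr <- matrix(rnorm(10 * 30), 10, 30,
                   dimnames = list(paste0("g", 1:10), paste0("S", 1:30)))
    mes <- module_eigengenes(expr, setNames(rep(1L, 10), rownames(expr)))
    ev <- eigen(tcrossprod(t(scale(t(expr)))), symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(mes$ME1$variance_explained, ev[1] / sum(ev),
                 tolerance = 1e-10)
    expect_gte(mes$ME1$variance_explained, max(ev[-1]) / sum(ev))
  }
})

test_that("modules with fewer than 2 genes are rejected", {
  expr <- matrix(rnorm(30), 3, 10,
                 dimnames = list(paste0("g", 1:3), paste0("S", 1:10)))
  expect_error(module_eigengenes(expr, c(g1 = 1L, g2 = 1L, g3 = 2L)),
               "fewer than 2")
})

test_that("trait correlation reproduces the closed-form t test at n = 3", {
  s <- paste0("S", 1:3)
  x <- c(-1, 0, 1)
  z <- c(1, -2, 1)                       # orthogonal to x
  y <- 0.5 * x / sd(x) + sqrt(0.75) * z / sd(z)   # cor(x, y) = 0.5 exactly
  mes <- make_me_set(list(ME1 = x), s)
  tab <- eigengene_trait_correlation(
    mes, data.frame(sample_id = s, trait = y))
  expect_equal(tab$r, 0.5, tolerance = 1e-12)
  # two-sided tail of t(1) (Cauchy): p = 1 - 2 atan(t) / pi with t = 1/sqrt(3)
  expect_equal(tab$p_value, 2 / 3, tolerance = 1e-12)
})

test_that("a trait identical to the eigengene gives r = 1, p ~ 0", {
  s <- paste0("S", 1:30)
  set.seed(2)
  v <- rnorm(30)
  mes <- make_me_set(list(ME1 = v), s)
  tab <- eigengene_trait_correlation(
    mes, data.frame(sample_id = s, same = v / sd(v)))
  expect_equal(tab$r, 1, tolerance = 1e-12)
  expect_lt(tab$p_value, 1e-12)
})

test_that("categorical traits are encoded as indicators and constants flagged", {
  s <- paste0("S", 1:12)
  set.seed(3)
  v <- rnorm(12)
  mes <- make_me_set(list(ME1 = v), s)
  samples <- data.frame(sample_id = s,
                        sex = rep(c("F", "M"), 6),
                        region = rep(c("DFC", "HIP", "STR"), 4),
                        flat = 1)
  expect_warning(tab <- eigengene_trait_correlation(mes, samples), "flat")
  expect_setequal(tab$trait,
                  c("sex", "region=DFC", "region=HIP", "region=STR"))
  sex01 <- as.numeric(factor(samples$sex)) - 1
  expect_equal(tab$r[tab$trait == "sex"], cor(mes$ME1$eigengene, sex01))
})

test_that("correlation p-values agree with a permutation null", {
  s <- paste0("S", 1:15)
  set.seed(4)
  v <- rnorm(15)
  y <- 0.6 * scale(v)[, 1] + rnorm(15, sd = 0.8)
  mes <- make_me_set(list(ME1 = v), s)
  tab <- eigengene_trait_correlation(mes, data.frame(sample_id = s, y = y))
  set.seed(99)
  r_obs <- abs(tab$r)
  null <- replicate(10000, abs(cor(v, sample(y))))
  p_perm <- mean(null >= r_obs)
  se <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(tab$p_value - p_perm), 4 * se + 1e-4)
})

test_that("matching a partition against itself is the identity", {
  fx <- small_dataset(seed = 10)
  fit <- coexnet(fx$data$expr, power = 6)
  mods <- modules(fit)
  ml <- match_labels(mods, mods)
  expect_identical(ml$assignment, mods)
  # idempotence
  expect_identical(match_labels(mods, ml$assignment)$assignment, mods)
})

test_that("significant overlap inherits the reference label", {
  genes <- sprintf("G%03d", 1:100)
  ref <- setNames(rep(0L, 100), genes)
  ref[1:30] <- 1L
  tst <- setNames(rep(0L, 100), genes)
  tst[c(1:25, 90:94)] <- 1L
  # exact tail: sum over k = 25..30 of C(30,k) C(70,30-k) / C(100,30)
  p_exact <- sum(choose(30, 25:30) * choose(70, 5:0)) / choose(100, 30)
  expect_lt(p_exact, 1e-10)
  ml <- match_labels(ref, tst)
  expect_equal(ml$pairs$p[1], p_exact, tolerance = 1e-10)
  expect_equal(unname(ml$assignment[c(1:25, 90:94)]), rep(1L, 30))
})

test_that("non-overlapping test modules receive fresh labels", {
  genes <- sprintf("G%03d", 1:100)
  ref <- setNames(c(rep(1L, 30), rep(2L, 30), rep(0L, 40)), genes)
  tst <- setNames(rep(0L, 100), genes)
  tst[61:95] <- 1L                       # inside ref background only
  ml <- match_labels(ref, tst)
  expect_equal(unname(unique(ml$assignment[61:95])), 3L)  # after max(ref)
  expect_error(match_labels(ref, setNames(1L, "other")), "disjoint")
})
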