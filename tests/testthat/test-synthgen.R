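test_that("identical config and seed give bit-identical datasets", {
  cfg <- synth_config(150, 40, module_sizes = c(60, 50),
                      trait_spec = list(list(name = "age", module = 1,
                                             strength = 0.8)),
                      seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$truth$assignment, d2$truth$assignment)
  d3 <- generate_dataset(synth_config(150, 40, module_sizes = c(60, 50),
                                      seed = 12))
  expect_false(identical(d1$expr, d3$expr))
})

test_that("module sizes, background count and config validation", {
  cfg <- synth_config(100, 20, module_sizes = c(50, 40),
                      background_fraction = 0.1, seed = 1)
  d <- generate_dataset(cfg)
  expect_equal(unname(table(d$truth$assignment)[c("0", "1", "2")]),
               c(10L, 50L, 40L), ignore_attr = TRUE)
  expect_equal(nrow(d$expr), 100)
  expect_equal(ncol(d$expr), 20)
  expect_error(synth_config(100, 20, module_sizes = c(50, 40),
                            background_fraction = 0.5, seed = 1),
               "inconsistent sizes")
  expect_error(synth_config(100, 20, module_sizes = c(50, 0), seed = 1),
               "module size")
  expect_error(synth_config(100, 20, c(50, 40), noise_sd = -1), "noise_sd")
})

test_that("noiseless single-module data has perfect within-module correlation", {
  cfg <- synth_config(30, 25, module_sizes = 30, noise_sd = 0,
                      background_fraction = 0, seed = 3)
  d <- generate_dataset(cfg)
  cc <- cor(t(d$expr))
  expect_true(all(abs(abs(cc) - 1) < 1e-12))
})

test_that("with small noise within-module correlations dominate between", {
  fx <- small_dataset(seed = 5, noise_sd = 0.1)
  d <- fx$data
  cc <- cor(t(d$expr))
  a <- d$truth$assignment
  within <- cc[a == 1, a == 1]
  between <- cc[a == 1, a == 2]
  expect_gt(min(abs(within)), 0.9)
  expect_lt(max(abs(between)), 0.5)
})

test_that("generated traits approach the configured correlation strength", {
  cfg <- synth_config(60, 500, module_sizes = c(30, 20),
                      trait_spec = list(list(name = "age", module = 1,
                                             strength = 0.7),
                                        list(name = "ph", module = 2,
                                             strength = -0.4)),
                      seed = 9)
  d <- generate_dataset(cfg)
  expect_lt(abs(cor(d$samples$age, d$truth$latent_profiles[1, ]) - 0.7), 0.1)
  expect_lt(abs(cor(d$samples$ph, d$truth$latent_profiles[2, ]) + 0.4), 0.1)
})

test_that("marker lists are seeded subsets of their stated module", {
  cfg <- synth_config(100, 20, module_sizes = c(50, 40),
                      marker_spec = list("1" = 20), seed = 2)
  d <- generate_dataset(cfg)
  mk <- generate_marker_collection(d$truth, cfg)
  expect_length(mk$markers_M1, 20)
  expect_true(all(d$truth$assignment[mk$markers_M1] == 1))
  cfg2 <- synth_config(100, 20, module_sizes = c(50, 40),
                       marker_spec = list("1" = 20), seed = 4)
  mk2 <- generate_marker_collection(d$truth, cfg2)
  expect_false(identical(mk, mk2))
  expect_true(all(d$truth$assignment[mk2$markers_M1] == 1))
  expect_length(generate_marker_collection(
    d$truth, synth_config(100, 20, c(50, 40), seed = 1)), 0)
  expect_error(generate_marker_collection(
    d$truth, synth_config(100, 20, c(50, 40),
                          marker_spec = list("2" = 41), seed = 1)),
    "exceeds module")
})

test_that("risk lists respect the enrichment fraction and have no duplicates", {
  cfg <- synth_config(100, 20, module_sizes = c(50, 40),
                      risk_spec = list(module = 1, size = 30, fraction = 1),
                      seed = 6)
  d <- generate_dataset(cfg)
  rl <- generate_risk_list(d$truth, cfg)
  expect_length(rl, 30)
  expect_false(anyDuplicated(rl) > 0)
  expect_true(all(d$truth$assignment[rl] == 1))

  cfg0 <- synth_config(100, 20, module_sizes = c(50, 40),
                       risk_spec = list(module = 1, size = 0, fraction = 1),
                       seed = 6)
  expect_length(generate_risk_list(d$truth, cfg0), 0)
  cfg_half <- synth_config(100, 20, module_sizes = c(50, 40),
                           risk_spec = list(module = 1, size = 20,
                                            fraction = 0.5), seed = 6)
  rl_half <- generate_risk_list(d$truth, cfg_half)
  # half the list is targeted at module 1; the uniform remainder can add more
  expect_gte(sum(d$truth$assignment[rl_half] == 1), 10)
  expect_length(rl_half, 20)
  expect_error(generate_risk_list(
    d$truth, synth_config(100, 20, c(50, 40),
                          risk_spec = list(module = 1, size = 101,
                                           fraction = 0), seed = 1)),
    "universe")
})

test_that("low-expression background genes fall below the filter threshold", {
  cfg <- synth_config(200, 30, module_sizes = c(60, 40),
                      low_expr_fraction = 0.5, seed = 8)
  d <- generate_dataset(cfg)
  means <- rowMeans(d$expr)
  expect_equal(sum(means < 6), 50)   # half of the 100 background genes
})

test_that("dataset round-trips through the TSV writers", {
  fx <- small_dataset(seed = 7, module_sizes = c(40, 30), n_samples = 15)
  fx$data$truth$risk_list <- c("G0001", "G0002")
  dir <- withr::local_tempdir()
  write_dataset(fx$data, dir)
  back <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(back, fx$data$expr, tolerance = 1e-12)
  expect_identical(readLines(file.path(dir, "risk_list.txt")),
                   c("G0001", "G0002"))
})
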