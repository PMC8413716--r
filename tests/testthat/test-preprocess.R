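make_samples <- function(age_value, age_unit, region = "A",
                         RIN = 9, id = NULL) {
  n <- length(age_value)
  data.frame(sample_id = if (is.null(id)) sprintf("S%02d", seq_len(n))
             else id,
             age_value = age_value,
             age_unit = rep_len(age_unit, n),
             region = rep_len(region, n), RIN = rep_len(RIN, n),
             stringsAsFactors = FALSE)
}

test_that("probe collapsing keeps the max-mean probe per gene", {
  pm <- rbind(P1 = c(7.0, 7.2), P2 = c(6.1, 6.3), P3 = c(5, 5),
              P4 = c(9, 9))
  colnames(pm) <- c("S01", "S02")
  map <- data.frame(probe = c("P1", "P2", "P3"),
                    gene = c("GA", "GA", "GB"))
  out <- collapse_probes(pm, map)
  expect_equal(rownames(out), c("GA", "GB"))
  expect_equal(out["GA", ], pm["P1", ])   # mean 7.1 beats 6.2
  expect_equal(out["GB", ], pm["P3", ])   # single probe passthrough
  expect_false("P4" %in% rownames(out))   # unmapped probe dropped
  expect_error(collapse_probes(pm, map[0, ]), "empty")
})

test_that("probe collapsing yields one row per distinct mapped gene", {
  set.seed(1)
  pm <- matrix(rnorm(40 * 6, 8), 40,
               dimnames = list(sprintf("P%02d", 1:40),
                               sprintf("S%02d", 1:6)))
  map <- data.frame(probe = rownames(pm),
                    gene = paste0("G", sample(1:15, 40, replace = TRUE)))
  out <- collapse_probes(pm, map)
  expect_equal(nrow(out), length(unique(map$gene)))
})

test_that("sample QC keeps RIN >= 8 inclusively", {
  s <- make_samples(c(1, 2, 3), "years", RIN = c(8.0, 7.9, 9.5))
  kept <- filter_samples(s, filter_config())
  expect_equal(kept$sample_id, c("S01", "S03"))
  expect_equal(nrow(filter_samples(s[0, ], filter_config())), 0)
  s$RIN[1] <- NA
  expect_error(filter_samples(s, filter_config()), "RIN")
})

test_that("ages map to the default interval scheme at the boundaries", {
  s <- make_samples(age_value = c(10, 38, 5, 6.0, 39.9, 40.0),
                    age_unit = c("weeks_postconception",
                                 "weeks_postconception",
                                 "years", "years", "years", "years"))
  iv <- assign_intervals(s, interval_scheme())
  expect_equal(unname(iv),
               c("I-1", "I-2", "I-2", "I-3", "I-3", "I-4"))
})

test_that("out-of-scheme ages are flagged, not dropped; negative ages error", {
  s <- make_samples(c(5, 1), c("weeks_postconception", "years"))
  expect_warning(iv <- assign_intervals(s), "outside")
  expect_true(is.na(iv[["S01"]]) && iv[["S02"]] == "I-2")
  s$age_value[1] <- -1
  expect_error(assign_intervals(s), "negative age")
})

test_that("interval assignment partitions any cohort from 10 WPC on", {
  set.seed(42)
  ages <- c(runif(50, 10, 38), runif(50, 0, 90))
  s <- make_samples(ages, c(rep("weeks_postconception", 50),
                            rep("years", 50)))
  iv <- assign_intervals(s)
  expect_false(anyNA(iv))
  expect_equal(length(iv), 100)
})

test_that("the shipped YAML scheme equals the built-in default", {
  path <- system.file("extdata", "intervals_default.yaml",
                      package = "coexdev")
  sc <- read_interval_scheme(path)
  expect_equal(sc$label, interval_scheme()$label)
  expect_equal(sc$lower, interval_scheme()$lower, tolerance = 1e-12)
  expect_equal(sc$upper, interval_scheme()$upper)
})

test_that("gene filter applies the >= 6 rule to every region-interval group", {
  # 2 regions x 2 intervals, 3 samples each
  s <- make_samples(rep(c(1, 10), each = 6), "years",
                    region = rep(rep(c("A", "B"), each = 3), 2))
  sch <- interval_scheme(c("young", "old"), c(0, 6), c(6, Inf))
  expr <- matrix(8, nrow = 3, ncol = 12,
                 dimnames = list(c("G1", "G2", "G3"), s$sample_id))
  # G2: one group mean exactly 6.0 (kept, inclusive); G3: one group 5.99
  expr["G2", s$region == "B" & s$age_value == 10] <- 6.0
  expr["G3", s$region == "A" & s$age_value == 1] <- 5.99
  out <- filter_genes(expr, s, filter_config(), sch)
  expect_equal(rownames(out), c("G1", "G2"))
  # identity when everything passes, idempotent in general
  expect_equal(filter_genes(out, s, filter_config(), sch), out)
})

test_that("per-sample filter mode is stricter than the group-mean mode", {
  s <- make_samples(rep(1, 4), "years")
  sch <- interval_scheme("all", 0, Inf)
  expr <- matrix(c(5, 7, 7, 7), nrow = 1,
                 dimnames = list("G1", s$sample_id))  # mean 6.5, min 5
  expect_equal(nrow(filter_genes(expr, s, filter_config(), sch)), 1)
  expect_equal(nrow(filter_genes(expr, s,
                                 filter_config(per_sample = TRUE), sch)), 0)
})

test_that("an empty region-interval group is an error naming the group", {
  s <- make_samples(rep(1, 4), "years", region = "A")
  sch <- interval_scheme(c("young", "old"), c(0, 6), c(6, Inf))
  expr <- matrix(8, 2, 4, dimnames = list(c("G1", "G2"), s$sample_id))
  expect_error(filter_genes(expr, s, filter_config(), sch), "A x old")
})

test_that("the generator's low-expression genes are removed by the filter", {
  cfg <- synth_config(300, 40, module_sizes = c(80, 60),
                      low_expr_fraction = 0.25, seed = 13)
  d <- generate_dataset(cfg)
  s <- make_samples(rep(1, 40), "years", id = colnames(d$expr))
  sch <- interval_scheme("all", 0, Inf)
  out <- filter_genes(d$expr, s, filter_config(), sch)
  expect_equal(nrow(out), 300 - 40)  # a quarter of 160 background genes
  expect_true(all(rowMeans(out) >= 6))
})
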