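test_that("generation is deterministic in config + seed", {
  cfg <- generator_config("paper_like", n = 100, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$dataset$values, b$dataset$values)
  cfg2 <- generator_config("paper_like", n = 100, seed = 12)
  expect_false(identical(generate_cohort(cfg2)$dataset$values,
                         a$dataset$values))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_cohort(generator_config("chain", n = 50,
                                                            seed = 5)))
  expect_identical(runif(1), before)
})

test_that("discretization solver hits every marginal target", {
  cfg <- generator_config("paper_like", n = 791, seed = 1)
  m <- cfg$marginals
  for (i in seq_len(nrow(m))) {
    d <- cfg$discretization[[i]]
    if (is.null(d)) next
    expect_lt(abs(d$achieved["mean"] - m$mean[i]), 0.05,
              label = paste("mean error for", m$name[i]))
    expect_lt(abs(d$achieved["sd"] - m$sd[i]), 0.08,
              label = paste("sd error for", m$name[i]))
  }
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config("chain", n = 1), "n must be >= 2")
  # a non-positive-definite partial structure
  nm <- c("a", "b", "c")
  s <- matrix(0.8, 3, 3, dimnames = list(nm, nm)); diag(s) <- 0
  marg <- data.frame(name = nm, community = "X", role = "symptom",
                     mean = 0, sd = 1, min = -Inf, max = Inf)
  expect_error(generator_config("custom", n = 100, structure = s,
                                marginals = marg),
               "not positive definite")
})

test_that("independent preset yields near-zero pairwise correlations", {
  g <- generate_cohort(generator_config("independent", n = 5000, seed = 2,
                                        p = 8))
  r <- cor(g$dataset$values)
  off <- abs(r[upper.tri(r)])
  expect_gte(mean(off < 0.05), 0.95)
})

test_that("covariate frequencies match their configured probabilities", {
  g <- generate_cohort(generator_config("paper_like", n = 5000, seed = 3))
  v <- g$dataset$values
  expect_equal(mean(v$gender == 1), 0.759, tolerance = 0.02)
  expect_equal(mean(v$medication == 0), 0.578, tolerance = 0.03)
  # medicated groups score lower on depression severity than untreated
  expect_lt(mean(v$HAMD14[v$medication == 1]),
            mean(v$HAMD14[v$medication == 0]))
})

test_that("copula rank structure survives discretization", {
  # the latent correlation between two likert columns shows up as rank
  # correlation of the discretized scores (attenuated, same order)
  g <- generate_cohort(generator_config("paper_like", n = 5000, seed = 4))
  v <- g$dataset$values
  sig <- generator_config("paper_like", n = 5000, seed = 4)$sigma
  r_dms_ema <- cor(v$DMS, v$EMA, method = "spearman")
  r_dms_ctq <- cor(v$DMS, v$EA, method = "spearman")
  expect_gt(r_dms_ema, 0.4)
  expect_gt(sig["DMS", "EMA"], sig["DMS", "EA"])
  expect_lt(abs(r_dms_ctq), 0.05)  # trauma block is independent by design
})

test_that("descriptive moments match their definitions", {
  # two-point symmetric column: kurtosis 1 under the non-excess convention
  specs <- list(
    variable_spec("a", "continuous", community = "X", min_value = -1,
                  max_value = 1),
    variable_spec("b", "continuous", community = "X", min_value = 0,
                  max_value = 100))
  d <- cohort_dataset(data.frame(a = c(-1, 1, -1, 1), b = c(1, 2, 3, 4)),
                      specs)
  s <- summarize_cohort(d)
  a_row <- s$numeric[s$numeric$variable == "a", ]
  expect_equal(a_row$mean, 0)
  expect_equal(a_row$skewness, 0)
  expect_equal(a_row$kurtosis, 1)

  # frozen direct-moment oracle values for {1,2,3,4,100}
  expect_equal(sample_skewness(c(1, 2, 3, 4, 100)), 1.49753670333352,
               tolerance = 1e-12)
  expect_equal(sample_kurtosis(c(1, 2, 3, 4, 100)), 3.24671648930016,
               tolerance = 1e-12)
})

test_that("categorical descriptives report level counts and percentages", {
  specs <- list(
    variable_spec("x", "continuous", community = "X"),
    variable_spec("g", "categorical", community = "COV", role = "covariate",
                  levels = 0:1, labels = c("m", "f")))
  d <- cohort_dataset(data.frame(x = c(1, 2, 3, 4), g = c(0, 1, 1, 1)),
                      specs)
  s <- summarize_cohort(d)
  expect_equal(s$categorical$count, c(1, 3))
  expect_equal(s$categorical$percent, c(25, 75))
  expect_equal(s$categorical$label, c("m", "f"))
})

test_that("paper-like ISI totals land near the published shape", {
  kurt <- vapply(1:5, function(s) {
    v <- paper_cohort(s)$dataset$values
    sample_kurtosis(rowSums(v[, isi_items]))
  }, numeric(1))
  # reported ISI-total kurtosis is 2.278; generated cohorts stay nearby
  expect_true(all(abs(kurt - 2.278) < 0.5))
})

test_that("with_total_score sums items into one bounded column", {
  g <- generate_cohort(generator_config("paper_like", n = 50, seed = 9))
  tot <- with_total_score(g$dataset, isi_items, "ISI")
  expect_true("ISI" %in% vapply(tot$specs, `[[`, character(1), "name"))
  expect_false("DMS" %in% names(tot$values))
  expect_equal(tot$values$ISI, rowSums(g$dataset$values[, isi_items]))
  s <- tot$specs[[match("ISI", vapply(tot$specs, `[[`, character(1),
                                      "name"))]]
  expect_equal(c(s$min_value, s$max_value), c(0, 28))
})
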