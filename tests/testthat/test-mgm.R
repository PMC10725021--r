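test_that("EBIC formula matches direct arithmetic", {
  expect_equal(ebic(-100, 3, 100, 10, 0.25), 217.2694, tolerance = 1e-4)
  expect_equal(ebic(-100, 3, 100, 10, 0), 213.8155, tolerance = 1e-4)
  expect_equal(ebic(-123.4, 0, 50, 7, 0.5), 246.8)  # k = 0: -2 loglik
  expect_error(ebic(-100, -1, 100, 10, 0.25), "non-negative")
})

test_that("estimation config validates its ranges", {
  expect_error(estimation_config(gamma = 0.7), "gamma")
  expect_error(estimation_config(lambda_min_ratio = 2), "lambda_min_ratio")
  expect_equal(estimation_config()$gamma, 0.25)
  expect_equal(estimation_config()$rule, "AND")
})

gaussian_cohort <- function(values) {
  specs <- lapply(names(values), variable_spec, var_type = "continuous",
                  community = "X", role = "symptom")
  cohort_dataset(as.data.frame(values), specs)
}

test_that("fit_node recovers a constructed regression", {
  set.seed(10)
  n <- 500
  x <- rnorm(n)
  noise <- matrix(rnorm(n * 5), n, 5)
  y <- x + rnorm(n, sd = 0.01)
  d <- gaussian_cohort(c(list(y = y, x = x),
                         setNames(asplit(noise, 2), paste0("z", 1:5))))
  fit <- fit_node("y", d)
  expect_gt(fit$aggregates["x"], 0.9)
  expect_true(all(fit$aggregates[paste0("z", 1:5)] == 0))
  expect_equal(unname(fit$signs["x"]), 1)
})

test_that("the all-zero end of the path scores the null model", {
  set.seed(11)
  d <- gaussian_cohort(list(a = rnorm(100), b = rnorm(100),
                            c = rnorm(100)))
  fit <- fit_node("a", d)
  ys <- (d$values$a - mean(d$values$a)) / sd(d$values$a)
  s2 <- mean((ys - mean(ys))^2)
  ll_null <- -100 / 2 * (log(2 * pi * s2) + 1)
  expect_equal(fit$path$k[1L], 0)
  expect_equal(fit$path$ebic[1L], -2 * ll_null, tolerance = 1e-8)
})

test_that("independent data yield empty neighborhoods", {
  for (s in 1:5) {
    g <- generate_cohort(generator_config("independent", n = 1000,
                                          seed = s, p = 6))
    net <- estimate_network(g$dataset)
    expect_equal(sum(net$weights != 0), 0,
                 label = paste("edges at seed", s))
  }
})

test_that("chain structure is recovered exactly", {
  for (s in 1:3) {
    g <- generate_cohort(generator_config("chain", n = 2000, seed = s,
                                          p = 3, rho = 0.3))
    net <- estimate_network(g$dataset)
    nz <- net$weights != 0
    expect_true(nz["V1", "V2"] && nz["V2", "V3"] && !nz["V1", "V3"],
                label = paste("chain recovery at seed", s))
    expect_gt(net$weights["V1", "V2"], 0)  # positive partials, signed +
  }
})

test_that("network invariants hold on a mixed paper-like fit", {
  g <- paper_cohort(1)
  td <- npn_transform(g$dataset, rule = "skewed")$transformed
  net <- estimate_network(td)
  # exact symmetry, zero diagonal
  expect_identical(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
  # AND-rule audit: both nodewise aggregates nonzero behind every edge
  nz <- which(net$weights != 0 & upper.tri(net$weights), arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  for (k in seq_len(nrow(nz))) {
    expect_gt(net$nodewise[nz[k, 1], nz[k, 2]], 0)
    expect_gt(net$nodewise[nz[k, 2], nz[k, 1]], 0)
  }
  # categorical nodes: all incident edges unsigned with non-negative weight
  net_cov <- estimate_with_covariates(td, c("HAMD14", "medication"))
  i_med <- match("medication", net_cov$nodes)
  expect_true(all(!net_cov$sign_defined[i_med, -i_med]))
  expect_true(all(net_cov$weights[i_med, ] >= 0))
  expect_true(all(net_cov$roles[match(c("HAMD14", "medication"),
                                      net_cov$nodes)] == "covariate"))
})

test_that("raising gamma never adds edges", {
  g <- generate_cohort(generator_config("chain", n = 500, seed = 21,
                                        p = 5, rho = 0.3))
  e0 <- estimate_network(g$dataset, estimation_config(gamma = 0))
  e5 <- estimate_network(g$dataset, estimation_config(gamma = 0.5))
  expect_true(all(e5$weights[e0$weights == 0] == 0))
})

test_that("edge magnitudes track the true partial correlations", {
  nm <- paste0("V", 1:4)
  s <- matrix(0, 4, 4, dimnames = list(nm, nm))
  s["V1", "V2"] <- s["V2", "V1"] <- 0.15
  s["V2", "V3"] <- s["V3", "V2"] <- 0.25
  s["V3", "V4"] <- s["V4", "V3"] <- 0.35
  marg <- data.frame(name = nm, community = "X", role = "symptom",
                     mean = 0, sd = 1, min = -Inf, max = Inf)
  g <- generate_cohort(generator_config("custom", n = 5000, seed = 31,
                                        structure = s, marginals = marg))
  net <- estimate_network(g$dataset)
  expect_identical(unname(net$weights != 0), unname(g$truth$adjacency))
  ut <- upper.tri(s)
  expect_gt(cor(net$weights[ut], s[ut]), 0.95)
})

test_that("covariate nodes do not distort the symptom subgraph", {
  agree <- 0
  for (s in 1:5) {
    g <- generate_cohort(generator_config("chain", n = 2000, seed = 40 + s,
                                          p = 4, rho = 0.3))
    base <- estimate_network(g$dataset)
    set.seed(900 + s)
    v2 <- g$dataset$values
    v2$noisecov <- rnorm(nrow(v2))
    specs2 <- c(g$dataset$specs,
                list(variable_spec("noisecov", "continuous",
                                   community = "COVARIATE",
                                   role = "covariate")))
    aug <- estimate_with_covariates(cohort_dataset(v2, specs2), "noisecov")
    same <- identical(aug$weights[1:4, 1:4] != 0, base$weights != 0)
    agree <- agree + same
  }
  expect_gte(agree, 4)
})

test_that("a hub covariate induces no spurious edge between its neighbors", {
  # collider-free construction: C - A and C - B edges, A - B absent
  nm <- c("A", "B", "C")
  s <- matrix(0, 3, 3, dimnames = list(nm, nm))
  s["C", "A"] <- s["A", "C"] <- 0.4
  s["C", "B"] <- s["B", "C"] <- 0.4
  marg <- data.frame(name = nm, community = "X", role = "symptom",
                     mean = 0, sd = 1, min = -Inf, max = Inf)
  hits <- 0
  for (seed in 1:5) {
    g <- generate_cohort(generator_config("custom", n = 2000, seed = seed,
                                          structure = s, marginals = marg))
    net <- estimate_network(g$dataset)
    hits <- hits + (net$weights["A", "B"] == 0)
  }
  expect_gte(hits, 4)
})

test_that("degenerate estimation inputs are rejected", {
  g <- generate_cohort(generator_config("chain", n = 5, seed = 1, p = 3))
  expect_error(estimate_network(g$dataset), "n > 10")
  g2 <- generate_cohort(generator_config("chain", n = 100, seed = 1, p = 2))
  expect_error(estimate_network(g2$dataset), ">= 3 variables")
  v <- data.frame(a = rnorm(50), b = rnorm(50), c = rep(1, 50))
  specs <- lapply(names(v), variable_spec, var_type = "continuous",
                  community = "X")
  d <- cohort_dataset(v, specs, check_constant = FALSE)
  expect_error(estimate_network(d), "constant column 'c'")
})
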