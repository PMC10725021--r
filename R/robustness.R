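# Case-dropping bootstrap stability (CS coefficients) for centrality
# indices, and nonparametric bootstrap confidence intervals for edge
# weights.

#' Configure stability and accuracy bootstraps
#'
#' @param n_boot Bootstrap replicates (default 1000).
#' @param drop_proportions Strictly increasing grid of case-drop fractions
#'   in (0, 1); default 0.05 to 0.75 in steps of 0.05.
#' @param cor_threshold Correlation with the full-sample index that a
#'   subsampled index must maintain (default 0.7).
#' @param prob_level Probability with which the threshold must be
#'   maintained (default 0.95; operationalized as the empirical 5th
#'   percentile of replicate correlations).
#' @param cs_pass CS value conventionally required for "stable" (0.25).
#' @param seed Master seed; per-replicate seeds are derived from it so
#'   results do not depend on execution order.
#' @return An object of class `psychnet_stabcfg`.
#' @export
stability_config <- function(n_boot = 1000,
                             drop_proportions = seq(0.05, 0.75, by = 0.05),
                             cor_threshold = 0.7, prob_level = 0.95,
                             cs_pass = 0.25, seed = 1) {
  if (any(diff(drop_proportions) <= 0) ||
      any(drop_proportions <= 0) || any(drop_proportions >= 1))
    stop("drop_proportions must be strictly increasing within (0, 1)",
         call. = FALSE)
  for (v in c(cor_threshold, prob_level, cs_pass))
    if (v <= 0 || v >= 1)
      stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  structure(
    list(n_boot = as.integer(n_boot), drop_proportions = drop_proportions,
         cor_threshold = cor_threshold, prob_level = prob_level,
         cs_pass = cs_pass, seed = as.integer(seed)),
    class = "psychnet_stabcfg")
}

#' Correlation-stability (CS) coefficient
#'
#' Given replicate-by-proportion correlations between subsampled and
#' full-sample centrality indices, the CS coefficient is the largest drop
#' proportion `p` in the grid such that for every grid proportion
#' `q <= p` the empirical `(1 - prob_level)` quantile of replicate
#' correlations at `q` is at least `cor_threshold`; it is 0 when the
#' condition already fails at the smallest proportion. The "for all
#' q <= p" guard keeps a non-contiguous pass region from inflating the
#' coefficient.
#'
#' @param correlations Numeric matrix, replicates in rows, one column per
#'   drop proportion (column names or `config$drop_proportions` give the
#'   grid). Undefined correlations must already be coded 0.
#' @param config A [stability_config()].
#' @return The CS coefficient (a value of the grid, or 0).
#' @export
cs_coefficient <- function(correlations, config = stability_config()) {
  if (is.null(dim(correlations)) || !nrow(correlations) ||
      !ncol(correlations))
    stop("correlations must be a non-empty replicate x proportion matrix",
         call. = FALSE)
  props <- if (!is.null(colnames(correlations)))
    as.numeric(colnames(correlations)) else config$drop_proportions
  if (length(props) != ncol(correlations))
    stop("cannot determine the drop-proportion grid", call. = FALSE)
  q <- apply(correlations, 2L,
             stats::quantile, probs = 1 - config$prob_level, names = FALSE)
  pass <- q >= config$cor_threshold
  cs <- 0
  for (i in seq_along(props)) {
    if (!pass[i]) break
    cs <- props[i]
  }
  cs
}

centrality_index_matrix <- function(network) {
  ct <- centrality(network)
  cbind(strength = ct$strength,
        expected_influence = ct$expected_influence,
        bridge_strength = ct$bridge_strength,
        bridge_expected_influence = ct$bridge_expected_influence)
}

replicate_seeds <- function(master, k) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Case-dropping bootstrap stability of centrality indices
#'
#' For each drop proportion and replicate, draws a without-replacement
#' subsample of the retained size, re-estimates the network, and records
#' the Pearson correlation of each centrality index (strength, expected
#' influence, bridge strength, bridge expected influence) with the
#' full-sample index vector. Replicates whose estimation fails or whose
#' index vector is constant yield an undefined correlation, which is
#' conservatively recorded as 0 (with a count in the report).
#'
#' @param data A `psychnet_cohort`.
#' @param est_config An [estimation_config()].
#' @param stab_config A [stability_config()].
#' @return A list of class `psychnet_stability` with `network` (the
#'   full-sample fit), `correlations` (list of replicate-by-proportion
#'   matrices per index), `cs` (named CS coefficients), and
#'   `n_undefined` (count of correlations coded 0).
#' @export
case_drop_bootstrap <- function(data, est_config = estimation_config(),
                                stab_config = stability_config()) {
  full <- estimate_network(data, est_config)
  full_idx <- centrality_index_matrix(full)
  idx_names <- colnames(full_idx)
  props <- stab_config$drop_proportions
  B <- stab_config$n_boot
  seeds <- matrix(replicate_seeds(stab_config$seed, B * length(props)),
                  B, length(props))
  cors <- lapply(idx_names, function(i)
    matrix(NA_real_, B, length(props),
           dimnames = list(NULL, format(props))))
  names(cors) <- idx_names
  n_undef <- 0L
  for (jp in seq_along(props)) {
    keep_n <- max(3L, round((1 - props[jp]) * data$n))
    for (b in seq_len(B)) {
      set.seed(seeds[b, jp])
      rows <- sample.int(data$n, keep_n)
      sub <- cohort_dataset(data$values[rows, , drop = FALSE], data$specs,
                            provenance = data$provenance,
                            check_constant = FALSE)
      rep_idx <- tryCatch(
        centrality_index_matrix(estimate_network(sub, est_config)),
        error = function(e) NULL)
      for (i in idx_names) {
        r <- if (is.null(rep_idx)) NA_real_
        else suppressWarnings(stats::cor(full_idx[, i], rep_idx[, i]))
        if (is.na(r)) { r <- 0; n_undef <- n_undef + 1L }
        cors[[i]][b, jp] <- r
      }
    }
  }
  if (n_undef > 0L)
    message("case_drop_bootstrap: ", n_undef,
            " undefined correlation(s) recorded as 0")
  cs <- vapply(cors, cs_coefficient, numeric(1), config = stab_config)
  structure(
    list(network = full, correlations = cors, cs = cs,
         n_undefined = n_undef, config = stab_config),
    class = "psychnet_stability")
}

#' @export
print.psychnet_stability <- function(x, ...) {
  cat("<case-dropping bootstrap stability>\n")
  for (i in names(x$cs))
    cat(sprintf("  CS(%s) = %.2f%s\n", i, x$cs[i],
                if (x$cs[i] > x$config$cs_pass) "  (stable)" else ""))
  invisible(x)
}

#' Bootstrap confidence intervals for edge weights
#'
#' Draws `n_boot` with-replacement resamples of full size, re-estimates
#' the network on each, and returns the empirical percentile interval of
#' every edge weight (zeros included when an edge is unselected in a
#' resample). Resamples whose estimation fails are dropped with a logged
#' count.
#'
#' @param data A `psychnet_cohort`.
#' @param config An [estimation_config()].
#' @param n_boot Number of resamples (default 1000).
#' @param seed Master seed.
#' @param prob_level Interval coverage (default 0.95).
#' @return A list of class `psychnet_edge_ci` with `edges` (data.frame
#'   `node_a`, `node_b`, `estimate`, `lower`, `upper`), `n_failed`, and
#'   `network` (the full-sample fit).
#' @export
edge_ci_bootstrap <- function(data, config = estimation_config(),
                              n_boot = 1000, seed = 1,
                              prob_level = 0.95) {
  full <- estimate_network(data, config)
  p <- length(full$nodes)
  ut <- which(upper.tri(full$weights))
  seeds <- replicate_seeds(seed, n_boot)
  wmat <- matrix(NA_real_, n_boot, length(ut))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(seeds[b])
    rows <- sample.int(data$n, data$n, replace = TRUE)
    sub <- cohort_dataset(data$values[rows, , drop = FALSE], data$specs,
                          provenance = data$provenance,
                          check_constant = FALSE)
    net <- tryCatch(estimate_network(sub, config), error = function(e) NULL)
    if (is.null(net)) { failed <- failed + 1L; next }
    wmat[b, ] <- net$weights[ut]
  }
  if (failed > 0L)
    message("edge_ci_bootstrap: ", failed, " failed resample(s) dropped")
  alpha <- (1 - prob_level) / 2
  lower <- apply(wmat, 2L, stats::quantile, probs = alpha, na.rm = TRUE,
                 names = FALSE)
  upper <- apply(wmat, 2L, stats::quantile, probs = 1 - alpha,
                 na.rm = TRUE, names = FALSE)
  ij <- which(upper.tri(full$weights), arr.ind = TRUE)
  structure(
    list(edges = data.frame(
           node_a = full$nodes[ij[, 1L]],
           node_b = full$nodes[ij[, 2L]],
           estimate = full$weights[ut],
           lower = lower, upper = upper,
           stringsAsFactors = FALSE),
         n_failed = failed, network = full),
    class = "psychnet_edge_ci")
}

#' @export
print.psychnet_edge_ci <- function(x, ...) {
  nz <- x$edges[x$edges$estimate != 0, ]
  cat(sprintf("<edge-weight bootstrap CIs> %d edges nonzero of %d pairs\n",
              nrow(nz), nrow(x$edges)))
  invisible(x)
}
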