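# Mixed graphical model estimation: per-node L1-penalized regressions
# (linear for continuous targets, multinomial logistic for categorical
# targets) with EBIC penalty selection, combined into a symmetric weighted
# conditional-dependence network.

#' Configure network estimation
#'
#' @param gamma EBIC hyperparameter in `[0, 0.5]`; 0 recovers the ordinary
#'   BIC, larger values penalize model size more and give sparser networks.
#'   Default 0.25.
#' @param rule Neighborhood combination rule: `"AND"` (default; an edge is
#'   kept only if both nodewise regressions select it) or `"OR"`.
#' @param nlambda Number of penalty values on the per-node path (default
#'   100, log-spaced from the smallest all-zero penalty downwards).
#' @param lambda_min_ratio Smallest penalty as a fraction of the per-node
#'   `lambda_max` (default `1e-3`).
#' @param standardize Z-score continuous predictors and responses within
#'   each nodewise fit, so edge weights are on a comparable standardized
#'   scale (default `TRUE`).
#' @param seed Optional seed recorded in the estimation metadata.
#'
#' @return An object of class `psychnet_estcfg`.
#' @export
estimation_config <- function(gamma = 0.25, rule = c("AND", "OR"),
                              nlambda = 100, lambda_min_ratio = 1e-3,
                              standardize = TRUE, seed = NULL) {
  rule <- match.arg(rule)
  if (!is.numeric(gamma) || gamma < 0 || gamma > 0.5)
    stop("gamma must lie in [0, 0.5]", call. = FALSE)
  if (nlambda < 2) stop("nlambda must be >= 2", call. = FALSE)
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("lambda_min_ratio must lie in (0, 1)", call. = FALSE)
  structure(
    list(gamma = gamma, rule = rule, nlambda = as.integer(nlambda),
         lambda_min_ratio = lambda_min_ratio, standardize = standardize,
         seed = seed),
    class = "psychnet_estcfg")
}

#' Extended Bayesian information criterion
#'
#' `-2 loglik + k log(n) + 2 gamma k log(p_cand)`; lower is better. With
#' `gamma = 0` this is the ordinary BIC.
#'
#' @param loglik Model log-likelihood.
#' @param k Number of nonzero (penalized) parameters.
#' @param n Sample size.
#' @param p_cand Number of candidate predictors (after dummy expansion).
#' @param gamma EBIC hyperparameter.
#' @return The EBIC score.
#' @export
ebic <- function(loglik, k, n, p_cand, gamma) {
  if (any(k < 0)) stop("k must be non-negative", call. = FALSE)
  if (n < 1 || p_cand < 1) stop("n and p_cand must be >= 1", call. = FALSE)
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p_cand)
}

# Dummy-expanded design matrix over all columns except `target`.
# Returns x (matrix), col_of (predictor name per design column).
build_design <- function(data, target, standardize) {
  nms <- spec_names(data)
  preds <- setdiff(nms, target)
  cols <- list(); col_of <- character(0)
  for (nm in preds) {
    s <- find_spec(data, nm)
    x <- data$values[[nm]]
    if (s$var_type == "categorical") {
      lev <- s$levels
      for (l in lev[-1L]) {
        cols[[length(cols) + 1L]] <- as.numeric(x == l)
        col_of <- c(col_of, nm)
      }
    } else {
      if (standardize) x <- (x - mean(x)) / stats::sd(x)
      cols[[length(cols) + 1L]] <- x
      col_of <- c(col_of, nm)
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- make.unique(col_of)
  list(x = x, col_of = col_of)
}

#' Fit one node's penalized neighborhood regression
#'
#' Regresses the target column on all other columns over an L1 path
#' (linear least squares for a continuous target, multinomial logistic for
#' a categorical target), scores every penalty by [ebic()] with `k` equal
#' to the nonzero-coefficient count and `p_cand` equal to the
#' dummy-expanded predictor count, and returns the penalty minimizing the
#' EBIC. Per-neighbor coefficients are aggregated as the mean of absolute
#' values over the dummy/class coefficients linking target and neighbor;
#' a sign is attached only when target and neighbor are both continuous.
#'
#' @param target Name of the target column.
#' @param data A `psychnet_cohort` (transformed upstream as appropriate).
#' @param config An [estimation_config()].
#' @return A list with `target`, `aggregates` (named vector over the other
#'   nodes), `signs` (named vector: -1/0/+1, 0 when undefined or
#'   unselected), `lambda`, `ebic`, `k`, `path` (per-lambda k and EBIC).
#' @export
fit_node <- function(target, data, config = estimation_config()) {
  s_t <- find_spec(data, target)
  for (s in data$specs)
    if (length(unique(data$values[[s$name]])) < 2L)
      stop("constant column '", s$name, "' must be screened before ",
           "estimation", call. = FALSE)
  des <- build_design(data, target, config$standardize)
  n <- data$n
  p_cand <- ncol(des$x)
  y <- data$values[[target]]
  categorical_target <- s_t$var_type == "categorical"
  if (categorical_target) {
    yf <- factor(y, levels = s_t$levels)
    fit <- tryCatch(
      glmnet::glmnet(des$x, yf, family = "multinomial",
                     nlambda = config$nlambda,
                     lambda.min.ratio = config$lambda_min_ratio,
                     standardize = FALSE),
      error = function(e)
        stop("multinomial fit failed for node '", target, "': ",
             conditionMessage(e), call. = FALSE))
    nl <- length(fit$lambda)
    betas <- lapply(fit$beta, as.matrix)  # one p_cand x nl matrix per class
    kvec <- Reduce(`+`, lapply(betas, function(b) colSums(b != 0)))
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    ll <- -dev / 2
  } else {
    ys <- if (config$standardize) (y - mean(y)) / stats::sd(y) else y
    fit <- glmnet::glmnet(des$x, ys, family = "gaussian",
                          nlambda = config$nlambda,
                          lambda.min.ratio = config$lambda_min_ratio,
                          standardize = FALSE)
    nl <- length(fit$lambda)
    beta <- as.matrix(fit$beta)
    kvec <- colSums(beta != 0)
    pred <- stats::predict(fit, des$x)
    rss <- colSums((ys - pred)^2)
    sigma2 <- rss / n
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  }
  scores <- ebic(ll, kvec, n, p_cand, config$gamma)
  best <- which.min(scores)  # ties resolve to the larger (sparser) penalty
  neighbors <- setdiff(spec_names(data), target)
  aggregates <- stats::setNames(numeric(length(neighbors)), neighbors)
  signs <- aggregates
  for (nm in neighbors) {
    cols <- which(des$col_of == nm)
    cf <- if (categorical_target)
      unlist(lapply(betas, function(b) b[cols, best]))
    else
      beta[cols, best]
    aggregates[nm] <- mean(abs(cf))
    if (!categorical_target &&
        find_spec(data, nm)$var_type == "continuous")
      signs[nm] <- sign(cf[1L])
  }
  list(target = target, aggregates = aggregates, signs = signs,
       lambda = fit$lambda[best], ebic = scores[best], k = kvec[best],
       loglik = ll[best],
       path = data.frame(lambda = fit$lambda, k = kvec, ebic = scores))
}

new_network <- function(weights, communities, roles, sign_defined,
                        config, n, nodewise = NULL) {
  nodes <- rownames(weights)
  stopifnot(identical(weights, t(weights)), all(diag(weights) == 0))
  if (any(!sign_defined & weights < 0))
    stop("unsigned edges must carry non-negative magnitudes",
         call. = FALSE)
  structure(
    list(nodes = nodes, communities = unname(communities),
         roles = unname(roles), weights = weights,
         sign_defined = sign_defined, config = config, n = n,
         nodewise = nodewise),
    class = "psychnet_network")
}

#' @export
print.psychnet_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<psychnet_network> %d nodes, %d edges (n = %s)\n",
              length(x$nodes), ne,
              if (is.null(x$n)) "?" else x$n))
  comm <- table(x$communities)
  cat("  communities:",
      paste(sprintf("%s(%d)", names(comm), comm), collapse = " "), "\n")
  invisible(x)
}

#' Estimate a mixed graphical model network
#'
#' Runs [fit_node()] for every variable and combines the nodewise
#' neighborhoods into a symmetric weighted network. Under the `"AND"` rule
#' an edge is kept only when both regressions select it; its weight is the
#' mean of the two per-neighbor aggregates. Edges with a categorical
#' endpoint have no sign (`sign_defined = FALSE`) and carry magnitudes
#' only; continuous-continuous edges take the shared sign of the two
#' coefficients, and the rare sign-conflicting pair is zeroed with a
#' warning.
#'
#' @param data A `psychnet_cohort` with at least 3 variables and n > 10.
#' @param config An [estimation_config()].
#' @return A `psychnet_network`.
#' @export
estimate_network <- function(data, config = estimation_config()) {
  nms <- spec_names(data)
  p <- length(nms)
  if (p < 3L) stop("network estimation needs >= 3 variables", call. = FALSE)
  if (data$n <= 10L) stop("network estimation needs n > 10", call. = FALSE)
  for (nm in nms)
    if (length(unique(data$values[[nm]])) < 2L)
      stop("constant column '", nm, "' must be dropped before estimation",
           call. = FALSE)
  fits <- lapply(nms, fit_node, data = data, config = config)
  names(fits) <- nms
  A <- matrix(0, p, p, dimnames = list(nms, nms))   # nodewise aggregates
  S <- matrix(0, p, p, dimnames = list(nms, nms))   # nodewise signs
  for (nm in nms) {
    A[nm, names(fits[[nm]]$aggregates)] <- fits[[nm]]$aggregates
    S[nm, names(fits[[nm]]$signs)] <- fits[[nm]]$signs
  }
  types <- spec_types(data)
  w <- matrix(0, p, p, dimnames = list(nms, nms))
  sgn_def <- matrix(TRUE, p, p, dimnames = list(nms, nms))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    both_cont <- types[i] == "continuous" && types[j] == "continuous"
    sgn_def[i, j] <- sgn_def[j, i] <- both_cont
    keep <- if (config$rule == "AND") A[i, j] > 0 && A[j, i] > 0
            else A[i, j] > 0 || A[j, i] > 0
    if (!keep) next
    wij <- mean(c(A[i, j], A[j, i]))
    if (both_cont) {
      ss <- c(S[i, j], S[j, i])
      ss <- ss[ss != 0]
      if (length(unique(ss)) > 1L) {
        warning("sign conflict on edge ", nms[i], "-", nms[j],
                "; edge set to zero", call. = FALSE)
        next
      }
      wij <- wij * unique(ss)
    }
    w[i, j] <- w[j, i] <- wij
  }
  new_network(weights = w,
              communities = spec_communities(data),
              roles = spec_roles(data),
              sign_defined = sgn_def,
              config = config, n = data$n, nodewise = A)
}

#' Estimate a covariate-adjusted network
#'
#' Identical to [estimate_network()] but with the named covariate columns
#' included as nodes whose role is recorded as `"covariate"`, so reports
#' can separate them from symptoms and psychosocial factors.
#'
#' @param data A `psychnet_cohort` containing the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param config An [estimation_config()].
#' @return A `psychnet_network`.
#' @export
estimate_with_covariates <- function(data, covariates,
                                     config = estimation_config()) {
  idx <- match(covariates, spec_names(data))
  if (anyNA(idx))
    stop("covariate column(s) not present: ",
         paste(covariates[is.na(idx)], collapse = ", "), call. = FALSE)
  for (i in idx) data$specs[[i]]$role <- "covariate"
  estimate_network(data, config)
}
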