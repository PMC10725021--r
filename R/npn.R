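#' Nonparanormal (rank-Gaussianizing) transformation
#'
#' Replaces each selected continuous column `x` by
#' `s * qnorm(T_delta(Fhat(x)))`, where `Fhat` is the empirical CDF
#' computed as average ranks divided by `n`, `T_delta` winsorizes into
#' `[delta_n, 1 - delta_n]` with the truncation constant
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`, and `s` rescales the result
#' to unit sample SD. Ties receive identical transformed values; the
#' transform is invariant under strictly increasing maps of the input.
#'
#' @param data A `psychnet_cohort`.
#' @param columns Columns to transform. `NULL` selects by `rule`.
#' @param rule Column-selection rule when `columns` is `NULL`:
#'   `"skewed"` (default) transforms continuous columns with
#'   `|skewness| > skew_threshold`; `"all"` transforms every continuous
#'   column; `"none"` transforms nothing.
#' @param skew_threshold Absolute moment-ratio skewness above which a
#'   column counts as skewed (default 1).
#'
#' @return A list of class `psychnet_transform` with `transformed`
#'   (the cohort with transformed columns), `truncation_level` (`delta_n`)
#'   and `columns_transformed`.
#' @export
npn_transform <- function(data, columns = NULL,
                          rule = c("skewed", "all", "none"),
                          skew_threshold = 1) {
  rule <- match.arg(rule)
  types <- spec_types(data)
  nms <- spec_names(data)
  if (is.null(columns)) {
    columns <- switch(
      rule,
      none = character(0),
      all = nms[types == "continuous"],
      skewed = {
        cont <- nms[types == "continuous"]
        cont[vapply(cont, function(nm)
          abs(sample_skewness(data$values[[nm]])) > skew_threshold,
          logical(1))]
      })
  } else {
    idx <- match(columns, nms)
    if (anyNA(idx))
      stop("unknown column(s): ", paste(columns[is.na(idx)], collapse = ", "),
           call. = FALSE)
    bad <- columns[types[idx] != "continuous"]
    if (length(bad))
      stop("cannot transform categorical column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- data$n
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  out <- data
  for (nm in columns) {
    x <- data$values[[nm]]
    if (length(unique(x)) < 2L)
      stop("column '", nm, "' has fewer than 2 distinct values",
           call. = FALSE)
    u <- rank(x, ties.method = "average") / n
    u <- pmin(pmax(u, delta), 1 - delta)
    g <- stats::qnorm(u)
    out$values[[nm]] <- g / stats::sd(g)
    # transformed values are unbounded; relax the declared range
    i <- match(nm, nms)
    out$specs[[i]]$min_value <- -Inf
    out$specs[[i]]$max_value <- Inf
  }
  structure(
    list(transformed = out, truncation_level = delta,
         columns_transformed = columns),
    class = "psychnet_transform")
}

#' @export
print.psychnet_transform <- function(x, ...) {
  cat(sprintf(
    "<npn transform> delta_n = %.5g; %d column(s) transformed\n",
    x$truncation_level, length(x$columns_transformed)))
  if (length(x$columns_transformed))
    cat("  ", paste(x$columns_transformed, collapse = ", "), "\n")
  invisible(x)
}
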