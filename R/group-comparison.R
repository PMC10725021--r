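# Kruskal-Wallis rank test with Dunn-type Bonferroni-corrected pairwise
# post-hoc comparisons (used for medication-group depression-severity
# contrasts).

#' Kruskal-Wallis test with Bonferroni post-hoc comparisons
#'
#' Computes the tie-corrected Kruskal-Wallis H statistic (via
#' [stats::kruskal.test()]) and Dunn-type pairwise z tests on the pooled
#' ranks, Bonferroni-adjusted over all group pairs. When every value is
#' tied the test degenerates to `H = 0`, `p = 1`.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels (coerced to factor), same length as
#'   `values`.
#' @return A list of class `psychnet_kw` with `H`, `df`, `p`, and
#'   `posthoc` (data.frame `group_a`, `group_b`, `z`, `p_raw`, `p_adj`).
#' @export
kruskal_wallis_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  if (anyNA(values) || anyNA(groups))
    stop("missing values are not allowed", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("every group needs >= 2 observations (offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")",
         call. = FALSE)
  g <- levels(groups)
  npairs <- choose(length(g), 2L)
  if (length(unique(values)) == 1L) {
    ph <- data.frame(t(utils::combn(g, 2L)), z = 0, p_raw = 1, p_adj = 1,
                     stringsAsFactors = FALSE)
    names(ph)[1:2] <- c("group_a", "group_b")
    return(structure(list(H = 0, df = length(g) - 1L, p = 1, posthoc = ph),
                     class = "psychnet_kw"))
  }
  kt <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  ph <- do.call(rbind, utils::combn(g, 2L, simplify = FALSE, FUN = function(pr) {
    a <- pr[1L]; b <- pr[2L]
    se <- sqrt(s2 * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = a, group_b = b, z = z, p_raw = p_raw,
               p_adj = min(1, p_raw * npairs), stringsAsFactors = FALSE)
  }))
  rownames(ph) <- NULL
  structure(
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value, posthoc = ph),
    class = "psychnet_kw")
}

#' @export
print.psychnet_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p))
  cat("Post-hoc (Dunn z, Bonferroni-adjusted):\n")
  print(format(x$posthoc, digits = 4), row.names = FALSE)
  invisible(x)
}
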