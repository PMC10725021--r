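#' Declare a single analysis variable
#'
#' A variable specification records everything the pipeline needs to know
#' about one column of a cohort table: its statistical type, admissible
#' values, the questionnaire community it belongs to (used for bridge
#' centrality, where each source scale is treated as one community), and its
#' analytic role.
#'
#' @param name Column name; must be unique within a dataset.
#' @param var_type `"continuous"` (includes ordinal items and subscale
#'   totals entered on a numeric scale) or `"categorical"`.
#' @param community Non-empty community label, e.g. `"ISI"`, `"EPQ"`,
#'   `"IRCDS"`, `"CTQ"`, `"SSRS"`, `"COVARIATE"`.
#' @param role One of `"symptom"`, `"factor"`, `"covariate"`.
#' @param min_value,max_value Numeric bounds for continuous variables
#'   (default unbounded). Values outside the bounds are rejected at load
#'   time.
#' @param levels Ordered integer codes of the categories (categorical only;
#'   at least two).
#' @param labels Optional character labels parallel to `levels`.
#'
#' @return An object of class `psychnet_varspec`.
#' @export
#' @examples
#' variable_spec("DIS", "continuous", community = "ISI", role = "symptom",
#'               min_value = 0, max_value = 4)
variable_spec <- function(name,
                          var_type = c("continuous", "categorical"),
                          community,
                          role = c("symptom", "factor", "covariate"),
                          min_value = -Inf, max_value = Inf,
                          levels = NULL, labels = NULL) {
  var_type <- match.arg(var_type)
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("variable name must be a non-empty string", call. = FALSE)
  if (!is.character(community) || length(community) != 1L || !nzchar(community))
    stop("community label must be non-empty for variable '", name, "'",
         call. = FALSE)
  if (var_type == "categorical") {
    if (is.null(levels) || length(levels) < 2L)
      stop("categorical variable '", name, "' needs >= 2 levels",
           call. = FALSE)
    levels <- as.integer(levels)
    if (anyDuplicated(levels))
      stop("duplicated level codes for variable '", name, "'", call. = FALSE)
    if (any(levels < 0L))
      stop("level codes must be non-negative integers ('", name, "')",
           call. = FALSE)
    if (!is.null(labels) && length(labels) != length(levels))
      stop("labels must match levels for variable '", name, "'",
           call. = FALSE)
  } else {
    if (!is.numeric(min_value) || !is.numeric(max_value) ||
        min_value > max_value)
      stop("continuous variable '", name, "' needs min_value <= max_value",
           call. = FALSE)
    levels <- NULL
  }
  structure(
    list(name = name, var_type = var_type, community = community,
         role = role, min_value = min_value, max_value = max_value,
         levels = levels, labels = labels),
    class = "psychnet_varspec"
  )
}

#' @export
print.psychnet_varspec <- function(x, ...) {
  rng <- if (x$var_type == "categorical")
    paste0("{", paste(x$levels, collapse = ","), "}")
  else
    paste0("[", x$min_value, ", ", x$max_value, "]")
  cat(sprintf("<varspec> %s  %s %s  community=%s role=%s\n",
              x$name, x$var_type, rng, x$community, x$role))
  invisible(x)
}

#' Assemble a validated cohort dataset
#'
#' Binds a participants-by-variables table to its variable specifications
#' and enforces the data-model invariants: one spec per column, unique
#' names, numeric cells, no missing values, every value inside its declared
#' range or level set.
#'
#' @param values A data.frame of numeric columns, one row per participant.
#' @param specs A list of [variable_spec()] objects, one per column, in
#'   column order.
#' @param provenance Free-text origin of the data (file path, or generator
#'   seed and preset).
#' @param check_constant If `TRUE` (default) a constant column is an error;
#'   constant columns cannot enter network estimation.
#'
#' @return An object of class `psychnet_cohort` with elements `values`,
#'   `specs`, `n`, `provenance`.
#' @export
cohort_dataset <- function(values, specs, provenance = "in-memory",
                           check_constant = TRUE) {
  if (!is.data.frame(values)) values <- as.data.frame(values)
  if (length(specs) != ncol(values))
    stop("spec count (", length(specs), ") != column count (",
         ncol(values), ")", call. = FALSE)
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicated variable names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(values) <- nm
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    x <- values[[j]]
    if (!is.numeric(x))
      stop("column '", s$name, "' is not numeric", call. = FALSE)
    if (anyNA(x)) {
      i <- which(is.na(x))[1L]
      stop("missing value at row ", i, ", column '", s$name,
           "' (apply the missingness policy before construction)",
           call. = FALSE)
    }
    if (s$var_type == "categorical") {
      bad <- which(!(x %in% s$levels))
      if (length(bad))
        stop("undeclared level ", x[bad[1L]], " at row ", bad[1L],
             ", column '", s$name, "'", call. = FALSE)
    } else {
      bad <- which(x < s$min_value | x > s$max_value)
      if (length(bad))
        stop("value ", x[bad[1L]], " out of range [", s$min_value, ", ",
             s$max_value, "] at row ", bad[1L], ", column '", s$name, "'",
             call. = FALSE)
    }
    if (check_constant && length(x) > 1L && length(unique(x)) == 1L)
      stop("column '", s$name, "' is constant and cannot be analyzed",
           call. = FALSE)
  }
  structure(
    list(values = values, specs = specs, n = nrow(values),
         provenance = provenance),
    class = "psychnet_cohort"
  )
}

#' @export
print.psychnet_cohort <- function(x, ...) {
  comm <- table(vapply(x$specs, function(s) s$community, character(1)))
  cat(sprintf("<psychnet_cohort> %d participants x %d variables\n",
              x$n, length(x$specs)))
  cat("  communities:",
      paste(sprintf("%s(%d)", names(comm), comm), collapse = " "), "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

spec_names <- function(data) vapply(data$specs, `[[`, character(1), "name")

spec_communities <- function(data)
  vapply(data$specs, `[[`, character(1), "community")

spec_types <- function(data)
  vapply(data$specs, `[[`, character(1), "var_type")

spec_roles <- function(data) vapply(data$specs, `[[`, character(1), "role")

find_spec <- function(data, name) {
  i <- match(name, spec_names(data))
  if (is.na(i)) stop("unknown variable '", name, "'", call. = FALSE)
  data$specs[[i]]
}

#' Restrict a cohort to a subset of variables
#'
#' @param data A `psychnet_cohort`.
#' @param names Variable names to keep, in the order given.
#' @return A `psychnet_cohort` with only those columns.
#' @export
subset_cohort <- function(data, names) {
  idx <- match(names, spec_names(data))
  if (anyNA(idx))
    stop("unknown variable(s): ", paste(names[is.na(idx)], collapse = ", "),
         call. = FALSE)
  cohort_dataset(data$values[, idx, drop = FALSE], data$specs[idx],
                 provenance = data$provenance)
}
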