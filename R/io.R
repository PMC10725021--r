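#' Read a variable-specification config file
#'
#' The config is a YAML (or JSON) file with a top-level `variables` list;
#' each entry carries `name`, `type`, `community`, `role`, and either
#' `min`/`max` (continuous) or `levels` + optional `labels` (categorical).
#'
#' @param path Path to the YAML/JSON spec file.
#' @return A list of [variable_spec()] objects.
#' @export
read_variable_spec <- function(path) {
  if (!file.exists(path))
    stop("spec file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else
    yaml::read_yaml(path)
  vars <- cfg$variables
  if (is.null(vars) || !length(vars))
    stop("spec file declares no variables: ", path, call. = FALSE)
  lapply(vars, function(v) {
    variable_spec(
      name = v$name,
      var_type = if (is.null(v$type)) "continuous" else v$type,
      community = v$community,
      role = if (is.null(v$role)) "factor" else v$role,
      min_value = if (is.null(v$min)) -Inf else as.numeric(v$min),
      max_value = if (is.null(v$max)) Inf else as.numeric(v$max),
      levels = v$levels,
      labels = v$labels
    )
  })
}

#' Write a variable-specification config file
#'
#' @param specs List of [variable_spec()] objects.
#' @param path Output path; `.yaml` and `.json` extensions select the
#'   dialect (default YAML).
#' @return `path`, invisibly.
#' @export
write_variable_spec <- function(specs, path) {
  vars <- lapply(specs, function(s) {
    v <- list(name = s$name, type = s$var_type, community = s$community,
              role = s$role)
    if (s$var_type == "categorical") {
      v$levels <- s$levels
      if (!is.null(s$labels)) v$labels <- s$labels
    } else {
      if (is.finite(s$min_value)) v$min <- s$min_value
      if (is.finite(s$max_value)) v$max <- s$max_value
    }
    v
  })
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(list(variables = vars), path, auto_unbox = TRUE,
                         digits = NA)
  else
    yaml::write_yaml(list(variables = vars), path)
  invisible(path)
}

#' Load a cohort table against its variable spec
#'
#' Reads a delimited text file with a header row, keeps the declared
#' analysis columns (extra columns are dropped with a notice), applies the
#' missingness policy, and validates every cell against its spec. Row order
#' is preserved.
#'
#' @param path Delimited data file with header.
#' @param spec_path Variable-spec config file ([read_variable_spec()]), or a
#'   list of [variable_spec()] objects.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param missing Missingness policy: `"listwise"` (default) drops any row
#'   with a missing declared value and logs the count; `"fail"` raises an
#'   error on the first missing cell.
#'
#' @return A validated [cohort_dataset()].
#' @export
read_dataset <- function(path, spec_path, delim = ",",
                         missing = c("listwise", "fail")) {
  missing <- match.arg(missing)
  if (!file.exists(path))
    stop("data file not found: ", path, call. = FALSE)
  specs <- if (is.character(spec_path)) read_variable_spec(spec_path)
           else spec_path
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  nm <- vapply(specs, `[[`, character(1), "name")
  absent <- setdiff(nm, names(raw))
  if (length(absent))
    stop("declared column(s) missing from ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(raw), nm)
  if (length(extra))
    message("read_dataset: ignoring ", length(extra),
            " undeclared column(s): ", paste(extra, collapse = ", "))
  raw <- raw[, nm, drop = FALSE]
  for (j in seq_along(raw)) {
    if (is.character(raw[[j]])) {
      conv <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(is.na(conv) & !is.na(raw[[j]]))
      if (length(bad))
        stop("non-numeric value '", raw[[j]][bad[1L]], "' at row ", bad[1L],
             ", column '", nm[j], "'", call. = FALSE)
      raw[[j]] <- conv
    }
  }
  incomplete <- !stats::complete.cases(raw)
  if (any(incomplete)) {
    if (missing == "fail") {
      i <- which(incomplete)[1L]
      j <- which(is.na(raw[i, ]))[1L]
      stop("missing value at row ", i, ", column '", nm[j], "'",
           call. = FALSE)
    }
    message("read_dataset: listwise deletion removed ", sum(incomplete),
            " row(s) with missing values")
    raw <- raw[!incomplete, , drop = FALSE]
    rownames(raw) <- NULL
  }
  cohort_dataset(raw, specs, provenance = path)
}

#' Write a cohort table as delimited text
#'
#' @param data A `psychnet_cohort`.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, delim = ",") {
  utils::write.table(data$values, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

network_sidecar_path <- function(path) sub("(\\.[^.]*)?$", ".json", path)

#' Write an estimated network to disk
#'
#' Writes a tab-separated edge list (`node_a`, `node_b`, `weight`,
#' `sign_defined`) containing only nonzero edges, plus a JSON sidecar
#' (same path with a `.json` extension) holding the node list, communities,
#' roles, and estimation metadata. Weights are serialized at full double
#' precision so that `read_network(write_network(x))` reproduces them
#' bit-exactly.
#'
#' @param network A `psychnet_network`.
#' @param path Output path for the edge-list TSV.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- network_edges(network)
  el$weight <- sprintf("%.17g", el$weight)
  ok <- tryCatch({
    utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write network to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  meta <- list(
    nodes = network$nodes,
    communities = as.list(stats::setNames(network$communities,
                                          network$nodes)),
    roles = as.list(stats::setNames(network$roles, network$nodes)),
    n = network$n,
    config = network$config[c("gamma", "rule", "nlambda",
                              "lambda_min_ratio", "standardize")],
    seed = network$config$seed
  )
  jsonlite::write_json(meta, network_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to the edge-list TSV (the JSON sidecar is located next
#'   to it).
#' @return A `psychnet_network`.
#' @export
read_network <- function(path) {
  side <- network_sidecar_path(path)
  if (!file.exists(path) || !file.exists(side))
    stop("network files not found: ", path, " / ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  nodes <- meta$nodes
  p <- length(nodes)
  w <- matrix(0, p, p, dimnames = list(nodes, nodes))
  sd_flag <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  el <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "character", "logical"))
  for (k in seq_len(nrow(el))) {
    i <- match(el$node_a[k], nodes); j <- match(el$node_b[k], nodes)
    w[i, j] <- w[j, i] <- as.numeric(el$weight[k])
    sd_flag[i, j] <- sd_flag[j, i] <- el$sign_defined[k]
  }
  new_network(weights = w,
              communities = unlist(meta$communities)[nodes],
              roles = unlist(meta$roles)[nodes],
              sign_defined = sd_flag,
              config = c(meta$config, list(seed = meta$seed)),
              n = meta$n)
}

#' Extract the nonzero edge list of a network
#'
#' @param network A `psychnet_network`.
#' @return A data.frame with columns `node_a`, `node_b`, `weight`,
#'   `sign_defined`, one row per nonzero edge (upper triangle).
#' @export
network_edges <- function(network) {
  w <- network$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(
    node_a = network$nodes[idx[, 1L]],
    node_b = network$nodes[idx[, 2L]],
    weight = w[idx],
    sign_defined = network$sign_defined[idx],
    stringsAsFactors = FALSE
  )
}

#' Write a data.frame as a TSV table
#'
#' Convenience wrapper used for centrality and stability outputs.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
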