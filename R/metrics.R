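# Centrality, bridge centrality over questionnaire communities, and
# shortest-pathway extraction on an estimated network.

#' Node centrality and bridge centrality
#'
#' For every node i: strength `s_i = sum_j |w_ij|`; 1-step expected
#' influence `ei_i = sum_j w_ij` (edges without a defined sign are stored
#' as magnitudes and therefore contribute their magnitude); bridge strength
#' `bs_i` and bridge expected influence `bei_i` restrict the same sums to
#' edges whose endpoints lie in different communities. For an all-positive
#' sign-defined network, strength and expected influence coincide, and
#' `s_i` decomposes exactly into within-community strength plus `bs_i`.
#'
#' @param network A `psychnet_network` with community labels.
#' @return A data.frame with columns `node`, `community`, `strength`,
#'   `expected_influence`, `bridge_strength`, `bridge_expected_influence`,
#'   in node order.
#' @export
centrality <- function(network) {
  comm <- network$communities
  if (is.null(comm) || any(is.na(comm)) || any(!nzchar(comm)))
    stop("every node needs a community label", call. = FALSE)
  w <- network$weights
  cross <- outer(comm, comm, `!=`)
  data.frame(
    node = network$nodes,
    community = comm,
    strength = rowSums(abs(w)),
    expected_influence = rowSums(w),
    bridge_strength = rowSums(abs(w) * cross),
    bridge_expected_influence = rowSums(w * cross),
    stringsAsFactors = FALSE)
}

# Distance matrix for pathway analysis: 1/|w| on nonzero edges (or unit
# steps for metric = "hops"), Inf elsewhere.
edge_distances <- function(network, metric) {
  w <- abs(network$weights)
  d <- ifelse(w > 0, if (metric == "hops") 1 else 1 / w, Inf)
  diag(d) <- Inf
  d
}

# TRUE if path a (node-name vector) orders lexicographically before b.
path_precedes <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Shortest pathway between two nodes
#'
#' Shortest path over nonzero edges with distances `1/|w|` (so strong
#' edges are short), or unit distances with `metric = "hops"`. Among
#' equal-distance paths the lexicographically smallest node-name sequence
#' is returned, which makes the result deterministic. Implemented as
#' label-correcting relaxation so the lexicographic tie-break is exact;
#' networks here are small (tens of nodes).
#'
#' @param network A `psychnet_network`.
#' @param source,target Distinct node names.
#' @param metric `"weighted"` (default) or `"hops"`.
#' @param tie_tol Relative tolerance for treating two path distances as
#'   tied.
#' @return A list of class `psychnet_path` with `source`, `target`, `path`
#'   (ordered node names; `NULL` when disconnected), `total_distance`, and
#'   `exists`.
#' @export
shortest_path <- function(network, source, target,
                          metric = c("weighted", "hops"),
                          tie_tol = 1e-9) {
  metric <- match.arg(metric)
  nodes <- network$nodes
  si <- match(source, nodes); ti <- match(target, nodes)
  if (is.na(si) || is.na(ti))
    stop("unknown node: ", if (is.na(si)) source else target, call. = FALSE)
  if (si == ti) stop("source and target must differ", call. = FALSE)
  d <- edge_distances(network, metric)
  p <- length(nodes)
  dist <- rep(Inf, p)
  paths <- vector("list", p)
  dist[si] <- 0; paths[[si]] <- nodes[si]
  repeat {
    changed <- FALSE
    for (i in seq_len(p)) {
      if (!is.finite(dist[i])) next
      for (j in seq_len(p)) {
        if (!is.finite(d[i, j])) next
        nd <- dist[i] + d[i, j]
        np <- c(paths[[i]], nodes[j])
        tie <- is.finite(dist[j]) &&
          abs(nd - dist[j]) <= tie_tol * max(1, abs(dist[j]))
        if (nd < dist[j] && !tie) {
          dist[j] <- nd; paths[[j]] <- np; changed <- TRUE
        } else if (tie && path_precedes(np, paths[[j]])) {
          paths[[j]] <- np; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  structure(
    list(source = source, target = target,
         path = paths[[ti]],
         total_distance = dist[ti],
         exists = is.finite(dist[ti])),
    class = "psychnet_path")
}

#' @export
print.psychnet_path <- function(x, ...) {
  if (x$exists)
    cat(sprintf("%s -> %s: %s (distance %.4g)\n", x$source, x$target,
                paste(x$path, collapse = " - "), x$total_distance))
  else
    cat(sprintf("%s -> %s: no path\n", x$source, x$target))
  invisible(x)
}

#' Union of shortest pathways between two node sets
#'
#' Computes [shortest_path()] for every source-target pair and returns the
#' union of traversed edges together with the intermediary nodes (nodes
#' appearing on at least one path, endpoints excluded) — the "via which
#' nodes do psychosocial factors reach the sleep symptoms" summary.
#'
#' @param network A `psychnet_network`.
#' @param sources,targets Disjoint non-empty sets of node names.
#' @param metric Passed to [shortest_path()].
#' @return A list of class `psychnet_pathways` with `paths` (list of
#'   `psychnet_path`), `edges` (data.frame `from`, `to`, `weight`), and
#'   `intermediaries` (character).
#' @export
pathway_subnetwork <- function(network, sources, targets,
                               metric = c("weighted", "hops")) {
  metric <- match.arg(metric)
  if (!length(sources) || !length(targets))
    stop("sources and targets must be non-empty", call. = FALSE)
  if (length(intersect(sources, targets)))
    stop("sources and targets must be disjoint", call. = FALSE)
  paths <- list()
  edge_key <- character(0)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  inter <- character(0)
  for (s in sources) for (t in targets) {
    pr <- shortest_path(network, s, t, metric = metric)
    paths[[paste(s, t, sep = "->")]] <- pr
    if (!pr$exists) next
    pp <- pr$path
    if (length(pp) > 2L) inter <- union(inter, pp[-c(1L, length(pp))])
    for (k in seq_len(length(pp) - 1L)) {
      a <- sort(c(pp[k], pp[k + 1L]))
      key <- paste(a, collapse = "|")
      if (!(key %in% edge_key)) {
        edge_key <- c(edge_key, key)
        edges <- rbind(edges, data.frame(
          from = a[1L], to = a[2L],
          weight = network$weights[a[1L], a[2L]],
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(paths = paths, edges = edges,
                 intermediaries = sort(inter)),
            class = "psychnet_pathways")
}

#' @export
print.psychnet_pathways <- function(x, ...) {
  ok <- sum(vapply(x$paths, `[[`, logical(1), "exists"))
  cat(sprintf("<pathways> %d/%d pairs connected, %d edges in union\n",
              ok, length(x$paths), nrow(x$edges)))
  if (length(x$intermediaries))
    cat("  intermediaries:", paste(x$intermediaries, collapse = ", "), "\n")
  invisible(x)
}

#' Screen factor domains for inclusion in the integrated network
#'
#' Applies the domain-screening rule used when building the integrated
#' model: a psychosocial domain is retained if and only if its
#' symptom-plus-domain network contains at least one nonzero edge between
#' a domain node and a symptom-community node. A domain with no such edge
#' (as found for childhood trauma) is excluded.
#'
#' @param domain_networks List of `psychnet_network`, each containing the
#'   symptom community plus exactly one factor domain.
#' @param symptom_community Community label of the symptom nodes (default
#'   `"ISI"`).
#' @return Character vector of retained domain community labels.
#' @export
select_domains <- function(domain_networks, symptom_community = "ISI") {
  retained <- character(0)
  for (net in domain_networks) {
    comm <- net$communities
    dom <- setdiff(unique(comm), c(symptom_community, "COVARIATE", "HAMD"))
    if (length(dom) != 1L)
      stop("each domain network must contain the symptom community plus ",
           "exactly one factor domain (got: ",
           paste(dom, collapse = ", "), ")", call. = FALSE)
    w <- net$weights
    sym <- comm == symptom_community
    d <- comm == dom
    if (any(w[sym, d, drop = FALSE] != 0))
      retained <- c(retained, dom)
  }
  retained
}
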