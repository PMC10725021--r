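# Shared fixtures and independent oracles used across the suite.

# Construct a network object directly from a weight matrix.
make_network <- function(weights, communities,
                         sign_defined = NULL, roles = NULL, n = 100L) {
  p <- nrow(weights)
  nodes <- rownames(weights)
  if (is.null(nodes)) {
    nodes <- LETTERS[seq_len(p)]
    dimnames(weights) <- list(nodes, nodes)
  }
  if (is.null(sign_defined))
    sign_defined <- matrix(TRUE, p, p, dimnames = dimnames(weights))
  if (is.null(roles)) roles <- rep("symptom", p)
  psychnet:::new_network(weights = weights, communities = communities,
                         roles = roles, sign_defined = sign_defined,
                         config = list(gamma = 0.25, rule = "AND"), n = n)
}

# Random small test network; weights drawn from a discrete set so that
# equal-distance path ties actually occur.
random_test_network <- function(p, seed, n_communities = 2) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(p)]
  w <- matrix(0, p, p, dimnames = list(nodes, nodes))
  pool <- c(0.1, 0.2, 0.25, 0.4, 0.5)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (stats::runif(1) < 0.5) {
      w[i, j] <- w[j, i] <- sample(pool, 1) * sample(c(-1, 1), 1)
    }
  }
  comm <- sample(paste0("comm", seq_len(n_communities)), p, replace = TRUE)
  make_network(w, comm)
}

# Exhaustive-summation centrality oracle (explicit loops, no matrix ops).
centrality_oracle <- function(network) {
  p <- length(network$nodes)
  w <- network$weights
  comm <- network$communities
  out <- data.frame(node = network$nodes, strength = 0,
                    expected_influence = 0, bridge_strength = 0,
                    bridge_expected_influence = 0)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    out$strength[i] <- out$strength[i] + abs(w[i, j])
    out$expected_influence[i] <- out$expected_influence[i] + w[i, j]
    if (comm[i] != comm[j]) {
      out$bridge_strength[i] <- out$bridge_strength[i] + abs(w[i, j])
      out$bridge_expected_influence[i] <-
        out$bridge_expected_influence[i] + w[i, j]
    }
  }
  out
}

# Brute-force shortest path: enumerate every simple path, take the minimal
# total distance, break ties by the lexicographically smallest node-name
# sequence. Independent of the package's relaxation algorithm.
path_oracle <- function(network, source, target,
                        metric = "weighted", tie_tol = 1e-9) {
  nodes <- network$nodes
  w <- abs(network$weights)
  d <- ifelse(w > 0, if (metric == "hops") 1 else 1 / w, Inf)
  best <- list(dist = Inf, path = NULL)
  lex_before <- function(a, b) {
    if (is.null(b)) return(TRUE)
    k <- min(length(a), length(b))
    for (i in seq_len(k)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  recurse <- function(at, visited, dist, path) {
    if (at == target) {
      tie <- is.finite(best$dist) &&
        abs(dist - best$dist) <= tie_tol * max(1, best$dist)
      if ((dist < best$dist && !tie) ||
          (tie && lex_before(path, best$path)))
        best <<- list(dist = dist, path = path)
      return(invisible())
    }
    for (nxt in nodes) {
      if (nxt %in% visited) next
      dd <- d[at, nxt]
      if (!is.finite(dd)) next
      recurse(nxt, c(visited, nxt), dist + dd, c(path, nxt))
    }
  }
  recurse(source, source, 0, source)
  best
}

# Direct rank-formula Kruskal-Wallis H with tie correction, written from
# scratch (no call into the package or kruskal.test).
kw_oracle <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  Rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Small paper-like generation cached per session for reuse across tests.
paper_cohort <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache) || cache$seed != seed)
      cache <<- list(seed = seed,
                     gen = generate_cohort(
                       generator_config("paper_like", n = 791, seed = seed)))
    cache$gen
  }
})

isi_items <- c("DIS", "DMS", "EMA", "DS", "IDF", "NIQoL", "Worry")
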