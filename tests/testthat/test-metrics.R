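test_that("centrality arithmetic matches the definitions", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.3
  w["A", "C"] <- w["C", "A"] <- -0.2
  net <- make_network(w, c("g1", "g1", "g2"))
  ct <- centrality(net)
  a <- ct[ct$node == "A", ]
  expect_equal(a$strength, 0.5)
  expect_equal(a$expected_influence, 0.1)
  # communities {A,B} vs {C}: bridge statistics of A
  expect_equal(a$bridge_strength, 0.2)
  expect_equal(a$bridge_expected_influence, -0.2)
  # exact strength decomposition: within + bridge
  expect_equal(a$strength, 0.3 + a$bridge_strength)
})

test_that("all-positive networks have EI = strength and bridge EI = bridge strength", {
  net <- random_test_network(6, seed = 1)
  net$weights <- abs(net$weights)
  ct <- centrality(net)
  expect_equal(ct$expected_influence, ct$strength)
  expect_equal(ct$bridge_expected_influence, ct$bridge_strength)
})

test_that("centrality matches the brute-force oracle on random graphs", {
  for (s in 1:200) {
    net <- random_test_network(sample(3:7, 1), seed = s,
                               n_communities = sample(1:3, 1))
    got <- centrality(net)
    want <- centrality_oracle(net)
    for (col in c("strength", "expected_influence", "bridge_strength",
                  "bridge_expected_influence"))
      expect_equal(got[[col]], want[[col]], tolerance = 1e-12,
                   label = paste(col, "seed", s))
  }
})

test_that("node permutation leaves every index unchanged", {
  net <- random_test_network(7, seed = 99)
  perm <- sample(7)
  net2 <- make_network(net$weights[perm, perm], net$communities[perm])
  a <- centrality(net); b <- centrality(net2)
  b <- b[match(a$node, b$node), ]
  expect_equal(a$strength, b$strength)
  expect_equal(a$bridge_expected_influence, b$bridge_expected_influence)
})

test_that("nodes without cross-community edges have zero bridge indices", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.5
  ct <- centrality(make_network(w, c("g1", "g1", "g2")))
  expect_equal(ct$bridge_strength, c(0, 0, 0))
  expect_equal(ct$bridge_expected_influence, c(0, 0, 0))
})

test_that("shortest paths prefer strong multi-hop routes over weak edges", {
  nm <- c("A", "B", "Z")
  w <- matrix(0, 3, 3, dimnames = list(nm, nm))
  w["A", "B"] <- w["B", "A"] <- 0.1     # direct distance 10
  w["A", "Z"] <- w["Z", "A"] <- 0.4     # 2.5
  w["Z", "B"] <- w["B", "Z"] <- 0.4     # 2.5
  net <- make_network(w, rep("g", 3))
  pr <- shortest_path(net, "A", "B")
  expect_equal(pr$path, c("A", "Z", "B"))
  expect_equal(pr$total_distance, 5)
  # the literal minimum-step reading takes the direct edge
  expect_equal(shortest_path(net, "A", "B", metric = "hops")$path,
               c("A", "B"))
})

test_that("two-node network returns its only edge", {
  w <- matrix(c(0, 0.25, 0.25, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  pr <- shortest_path(make_network(w, c("g", "g")), "A", "B")
  expect_equal(pr$total_distance, 4)
  expect_equal(pr$path, c("A", "B"))
})

test_that("disconnected pairs report exists = FALSE", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.5
  net <- make_network(w, rep("g", 3))
  pr <- shortest_path(net, "A", "C")
  expect_false(pr$exists)
  expect_error(shortest_path(net, "A", "A"), "differ")
  expect_error(shortest_path(net, "A", "nope"), "unknown node")
})

test_that("shortest paths equal exhaustive enumeration on random graphs", {
  for (s in 1:150) {
    net <- random_test_network(sample(4:7, 1), seed = 1000 + s)
    nodes <- net$nodes
    pair <- sample(nodes, 2)
    got <- shortest_path(net, pair[1], pair[2])
    want <- path_oracle(net, pair[1], pair[2])
    if (!got$exists) {
      expect_false(is.finite(want$dist), label = paste("seed", s))
    } else {
      expect_equal(got$total_distance, want$dist, tolerance = 1e-9,
                   label = paste("distance seed", s))
      expect_identical(got$path, want$path,
                       label = paste("path seed", s))
    }
  }
})

test_that("pathway subnetworks identify the unique hub intermediary", {
  nm <- c("s1", "s2", "h", "t1", "t2")
  w <- matrix(0, 5, 5, dimnames = list(nm, nm))
  for (a in c("s1", "s2")) { w[a, "h"] <- w["h", a] <- 0.5 }
  for (b in c("t1", "t2")) { w[b, "h"] <- w["h", b] <- 0.5 }
  net <- make_network(w, c("src", "src", "mid", "tgt", "tgt"))
  pw <- pathway_subnetwork(net, c("s1", "s2"), c("t1", "t2"))
  expect_identical(pw$intermediaries, "h")
  expect_true(all(vapply(pw$paths, function(p) length(p$path) == 3,
                         logical(1))))
  expect_equal(nrow(pw$edges), 4)
})

test_that("disconnected domains give an empty pathway union", {
  w <- matrix(0, 4, 4,
              dimnames = list(c("a", "b", "x", "y"),
                              c("a", "b", "x", "y")))
  w["a", "b"] <- w["b", "a"] <- 0.5
  w["x", "y"] <- w["y", "x"] <- 0.5
  net <- make_network(w, c("d1", "d1", "d2", "d2"))
  pw <- pathway_subnetwork(net, c("a", "b"), c("x", "y"))
  expect_equal(nrow(pw$edges), 0)
  expect_false(any(vapply(pw$paths, `[[`, logical(1), "exists")))
})

test_that("domain screening keeps only domains with symptom edges", {
  mk <- function(edge) {
    nm <- c("i1", "i2", "f1", "f2")
    w <- matrix(0, 4, 4, dimnames = list(nm, nm))
    w["i1", "i2"] <- w["i2", "i1"] <- 0.4
    w["f1", "f2"] <- w["f2", "f1"] <- 0.4
    if (edge) w["i2", "f1"] <- w["f1", "i2"] <- 0.2
    make_network(w, c("ISI", "ISI", "DOM", "DOM"))
  }
  expect_identical(select_domains(list(mk(TRUE))), "DOM")
  expect_identical(select_domains(list(mk(FALSE))), character(0))
  bad <- make_network(matrix(0, 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b"))),
                      c("ISI", "ISI"))
  expect_error(select_domains(list(bad)), "exactly one factor domain")
})

test_that("missing community labels are fatal for centrality", {
  net <- random_test_network(4, seed = 5)
  net$communities[2] <- ""
  expect_error(centrality(net), "community")
})
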