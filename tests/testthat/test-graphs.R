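# Canonical forms, automorphisms, orientations and connectivity.

test_that("canonical form is invariant under relabeling and idempotent", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(3:5, 1)
    L <- n * (n - 1)
    mask <- sample.int(2^L, 1) - 1L
    e <- mdlmotif:::.edgesFromMask(n, mask)
    sigma <- sample.int(n)
    e2 <- if (nrow(e)) cbind(sigma[e[, 1]], sigma[e[, 2]]) else e
    c1 <- canonicalForm(e, n)
    c2 <- canonicalForm(e2, n)
    expect_identical(c1$mask, c2$mask)
    expect_identical(c1$bits, c2$bits)
    # idempotence: canonicalizing the canonical representative is a no-op
    ce <- mdlmotif:::.edgesFromMask(n, c1$mask)
    expect_identical(canonicalForm(ce, n)$mask, c1$mask)
  }
})

test_that("canonical bitstrings match the worked small cases", {
  expect_identical(canonicalForm(rbind(c(1, 2)), 2)$bits, "10")
  # relabeled 3-cycles coincide
  b1 <- canonicalForm(rbind(c(1, 2), c(2, 3), c(3, 1)), 3)$bits
  b2 <- canonicalForm(rbind(c(3, 1), c(1, 2), c(2, 3)), 3)$bits
  b3 <- canonicalForm(rbind(c(2, 1), c(1, 3), c(3, 2)), 3)$bits
  expect_identical(b1, b2)
  expect_identical(b1, b3)
})

test_that("three-node digraphs fall into 13 weakly connected classes (independent oracle)", {
  # pure-R pairwise permutation isomorphism over all 64 labeled digraphs
  connected <- Filter(function(m) {
    e <- mdlmotif:::.edgesFromMask(3L, m)
    isWeaklyConnected(e, 3)
  }, 0:63)
  reps <- list()
  for (m in connected) {
    e <- mdlmotif:::.edgesFromMask(3L, m)
    found <- any(vapply(reps, function(r) isoOracle(e, r, 3), logical(1)))
    if (!found) reps[[length(reps) + 1]] <- e
  }
  expect_length(reps, 13)
  # and the canonical-mask route agrees with the oracle class count
  masks <- unique(vapply(connected, function(m) {
    e <- mdlmotif:::.edgesFromMask(3L, m)
    canonicalForm(e, 3)$mask
  }, integer(1)))
  expect_length(masks, 13)
})

test_that("canonical-mask isomorphism agrees with igraph on random 4-node pairs", {
  library(igraph)
  set.seed(23)
  for (rep in 1:60) {
    m1 <- sample.int(2^12, 1) - 1L
    m2 <- if (runif(1) < 0.5) m1 else sample.int(2^12, 1) - 1L
    e1 <- mdlmotif:::.edgesFromMask(4L, m1)
    e2 <- mdlmotif:::.edgesFromMask(4L, m2)
    if (runif(1) < 0.5 && nrow(e2)) { s <- sample.int(4); e2 <- cbind(s[e2[, 1]], s[e2[, 2]]) }
    oursSame <- canonicalForm(e1, 4)$mask == canonicalForm(e2, 4)$mask
    ig1 <- graph_from_data_frame(as.data.frame(e1), directed = TRUE, vertices = data.frame(1:4))
    ig2 <- graph_from_data_frame(as.data.frame(e2), directed = TRUE, vertices = data.frame(1:4))
    expect_identical(oursSame, isomorphic(ig1, ig2, method = "vf2"))
  }
})

test_that("automorphism and orientation counts match brute-force values", {
  expect_identical(automorphismCount(rbind(c(1, 2), c(2, 3), c(3, 1)), 3), 3L)
  expect_identical(automorphismCount(cliqueEdges(5), 5), 120L)
  expect_identical(automorphismCount(rbind(c(1, 2), c(2, 1)), 2), 2L)
  expect_equal(orientationCount(cliqueEdges(5), 5), 1)
  # reciprocal pair a<->b plus a->c, b->c: |Aut| = 2, three orientations
  fig <- rbind(c(1, 2), c(2, 1), c(1, 3), c(2, 3))
  expect_identical(automorphismCount(fig, 3), 2L)
  expect_equal(orientationCount(fig, 3), 3)
  expect_equal(orientationCount(rbind(c(1, 2), c(2, 3), c(3, 1)), 3), 2)
})

test_that("orientations times automorphisms equals n! for every 3- and 4-node graphlet", {
  for (gl in enumerateGraphlets(3, 4)) {
    expect_equal(gl@orientations * gl@aut, factorial(gl@n))
  }
})

test_that("weak connectivity handles the degenerate and disconnected cases", {
  expect_false(isWeaklyConnected(rbind(c(1, 2)), 3))        # node 3 isolated
  expect_true(isWeaklyConnected(rbind(c(1, 2), c(3, 2)), 3)) # 1 -> 2 <- 3
  expect_true(isWeaklyConnected(matrix(integer(), 0, 2), 1)) # single node
  expect_error(isWeaklyConnected(matrix(integer(), 0, 2), 0), "empty")
})

test_that("graphlet ids serialize and parse round-trip", {
  for (gl in enumerateGraphlets(2, 4)) {
    back <- graphletFromId(gl@id)
    expect_identical(back@mask, gl@mask)
    expect_identical(back@aut, gl@aut)
    # rendering to edges and re-canonicalizing lands on the same class
    expect_identical(graphlet(graphletEdges(gl), gl@n)@id, gl@id)
  }
  expect_error(graphletFromId("x3-zz"), "malformed")
})

test_that("directed graph container validates its invariants", {
  expect_error(directedGraph(rbind(c(1, 1))), "self-loops")
  expect_error(directedGraph(rbind(c(1, 2), c(1, 2))), "duplicate")
  g <- directedGraph(rbind(c("a", "b"), c("b", "a"), c("b", "c")))
  expect_identical(numNodes(g), 3L)
  expect_identical(numEdges(g), 3L)
  expect_identical(nodeLabels(g), c("a", "b", "c"))
  H <- asMultigraph(g)
  expect_identical(reciprocatedEdgeCount(H), 1L)
  expect_identical(nonReciprocatedEdgeCount(H), 1L)
  expect_equal(outDegrees(H), c(1, 2, 0))
})
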