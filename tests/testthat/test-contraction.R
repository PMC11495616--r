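# Subgraph contraction and codelength gains.

test_that("contraction merges shared neighbors into parallel multiedges", {
  # triangle + 4->1 and 3->5: worked reduction
  g <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 1), c(3, 5)), N = 5)
  st <- contract(reductionState(g, "ER"), 1:3, triangleGraphlet())
  expect_identical(nrow(st@H@A), 3L)
  sIdx <- match(st@supernodes[[1]]$id, st@nodeIds)
  i4 <- match(4L, st@nodeIds); i5 <- match(5L, st@nodeIds)
  expect_identical(st@H@A[i4, sIdx], 1L)
  expect_identical(st@H@A[sIdx, i5], 1L)
  expect_identical(sum(st@H@A), 2L)

  # two members pointing at the same external node: multiplicity 2
  g2 <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4)), N = 4)
  st2 <- contract(reductionState(g2, "ER"), 1:3, triangleGraphlet())
  sIdx <- match(st2@supernodes[[1]]$id, st2@nodeIds)
  expect_identical(st2@H@A[sIdx, match(4L, st2@nodeIds)], 2L)
  # node count after contraction: N(H) - n_s + 1
  expect_identical(nrow(st2@H@A), 4L - 3L + 1L)
})

test_that("overlap and isomorphism preconditions are enforced", {
  g <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4), c(4, 5), c(5, 3)), N = 5)
  st <- contract(reductionState(g, "ER"), 1:3, triangleGraphlet())
  expect_false(nonOverlapping(st, c(3, 4, 5)))
  expect_true(nonOverlapping(st, c(4, 5)))
  expect_error(contract(st, 3:5, triangleGraphlet()), "overlap")
  # wrong graphlet claim
  st0 <- reductionState(g, "ER")
  expect_error(contract(st0, c(1, 2, 4), triangleGraphlet()), "not isomorphic")
})

test_that("engine candidate gains equal full recomputation on 200+ contractions", {
  g <- randomDigraph(45, 220, 31)
  census <- subgraphCensus(g, sizes = 3:4)
  for (fam in c("ER", "CM", "RER", "RCM")) {
    rr <- greedyRun(g, census, fam, B = 3, seed = 77, logCandidates = 60)
    log <- attr(rr, "candidateLog")
    expect_gte(length(log$gain), 50)
    # rebuild the state right before each logged iteration and recompute
    states <- list(reductionState(g, fam, gammaSize = length(census@gamma)))
    for (t in seq_along(rr@contractions)) {
      states[[t + 1]] <- contract(states[[t]], rr@contractions[[t]]$members,
                                  graphletFromId(rr@contractions[[t]]$graphlet))
    }
    for (ci in seq_along(log$gain)) {
      st <- states[[log$iter[ci]]]
      gl <- census@gamma[[log$graphlet[ci]]]
      oracle <- contractionGain(st, log$subsets[[ci]], gl)
      expect_equal(log$gain[ci], oracle, tolerance = 1e-6)
    }
  }
})

test_that("gains are side-effect free and label-invariant", {
  g <- directedGraph(cliqueEdges(5), N = 5)
  cl5 <- graphlet(cliqueEdges(5), 5)
  st <- reductionState(g, "ER")
  g1 <- contractionGain(st, 1:5, cl5)
  g2 <- contractionGain(st, 1:5, cl5)
  expect_identical(g1, g2)
  # relabeled copy gives the same gain
  set.seed(2)
  sigma <- sample.int(5)
  gre <- directedGraph(cbind(sigma[g@edges[, 1]], sigma[g@edges[, 2]]), N = 5)
  expect_equal(contractionGain(reductionState(gre, "ER"), 1:5, cl5), g1,
               tolerance = 1e-9)
})

test_that("state invariants hold after every contraction", {
  g <- randomDigraph(30, 140, 17)
  census <- subgraphCensus(g, sizes = 3:4)
  rr <- greedyRun(g, census, "RCM", B = 5, seed = 3)
  st <- reductionState(g, "RCM", gammaSize = length(census@gamma))
  for (ct in rr@contractions) {
    eInternal <- sum(adjacencyMatrix(g)[ct$members, ct$members])
    Ebefore <- sum(st@H@A)
    st <- contract(st, ct$members, graphletFromId(ct$graphlet))
    expect_true(validObject(st))
    # edge conservation: contracting removes exactly the internal edges
    expect_identical(sum(st@H@A), Ebefore - eInternal)
    expect_identical(sum(diag(st@H@A)), 0L)
  }
})

test_that("plant-contract round trip restores the latent multigraph", {
  pm <- plantMotifs(40, 110, c("d5-fffff" = 3, "d3-19" = 2), seed = 6)
  st <- reductionState(pm$graph, "ER")
  set.seed(9)
  for (gt in sample(pm$groundTruth)) { # arbitrary contraction order
    st <- contract(st, gt$members, graphletFromId(gt$graphlet))
  }
  latent <- multigraph(pm$latent$A)
  expect_identical(nrow(st@H@A), nrow(latent@A))
  expect_identical(sum(st@H@A), sum(latent@A))
  # multiplicity multisets agree up to node relabeling
  expect_identical(sort(as.vector(st@H@A)), sort(as.vector(latent@A)))
  # latent codelength identity for the ER base
  expect_equal(baseEntropy(st@H, "ER") + modelComplexity(st@H, "ER"),
               baseEntropy(latent, "ER") + modelComplexity(latent, "ER"),
               tolerance = 1e-9)
})
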