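# Greedy search, batching, determinism and model selection.

test_that("runs are bit-for-bit reproducible under a fixed seed", {
  g <- randomDigraph(30, 130, 12)
  census <- subgraphCensus(g, sizes = 3)
  r1 <- greedyRun(g, census, "ER", B = 5, seed = 42)
  r2 <- greedyRun(g, census, "ER", B = 5, seed = 42)
  expect_identical(r1@trajectory, r2@trajectory)
  expect_identical(r1@contractions, r2@contractions)
  r3 <- greedyRun(g, census, "ER", B = 5, seed = 43)
  expect_false(identical(r1@trajectory, r3@trajectory))
})

test_that("graphs without censusable subgraphs return the initial state", {
  g <- directedGraph(rbind(c(1, 2)), N = 2)
  census <- subgraphCensus(g, sizes = 3)
  rr <- greedyRun(g, census, "ER", B = 5, seed = 1)
  expect_identical(rr@bestIteration, 0L)
  expect_length(rr@trajectory, 1)
  expect_length(motifIds(rr), 0)
})

test_that("the selected state is the trajectory minimum, not the final state", {
  g <- randomDigraph(35, 160, 21)
  census <- subgraphCensus(g, sizes = 3)
  rr <- greedyRun(g, census, "ER", B = 5, seed = 5)
  expect_gt(length(rr@trajectory), 1)
  expect_equal(rr@trajectory[rr@bestIteration + 1], min(rr@trajectory))
  expect_equal(min(rr@trajectory), totalCodeLength(rr@state), tolerance = 1e-6)
})

test_that("engine trajectories equal naive recomputation for every family", {
  g <- randomDigraph(40, 170, 7)
  census <- subgraphCensus(g, sizes = 3:4)
  for (fam in c("ER", "CM", "RER", "RCM")) {
    rr <- greedyRun(g, census, fam, B = 5, seed = 11)
    st <- reductionState(g, fam, gammaSize = length(census@gamma))
    Ls <- totalCodeLength(st)
    for (ct in rr@contractions) {
      st <- contract(st, ct$members, graphletFromId(ct$graphlet))
      Ls <- c(Ls, totalCodeLength(st))
    }
    expect_equal(Ls, rr@trajectory, tolerance = 1e-6)
  }
})

test_that("inferred occurrences are node-disjoint and induce their graphlets", {
  pm <- plantMotifs(60, 200, c("d5-fffff" = 4), seed = 3)
  gamma <- c(enumerateGraphlets(3, 3), list(graphletFromId(clique5Id)))
  census <- subgraphCensus(pm$graph, gamma = gamma, sizes = c(3, 5))
  rr <- greedyRun(pm$graph, census, "ER", B = 10, seed = 2)
  members <- lapply(rr@state@supernodes, `[[`, "members")
  expect_identical(anyDuplicated(unlist(members)), 0L)
  for (s in rr@state@supernodes) {
    expect_identical(inducedGraphletId(pm$graph, s$members), s$graphlet@id)
  }
})

test_that("batch sampling follows the survival semantics", {
  g <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4)), N = 6)
  census <- subgraphCensus(g, sizes = 3)
  gi <- which(census@counts > 0)
  occ <- list(occurrenceMatrix(census, gi[1]))
  st <- reductionState(g, "ER")
  set.seed(1)
  res <- sampleBatch(occ, st, B = 10)
  # |C_alpha| <= B and nothing overlapping: the whole list is batched and kept
  expect_length(res$batch, 2)
  expect_identical(nrow(res$occurrences[[1]]), 2L)
  # after contracting one triangle, its occurrence is discarded when drawn
  st2 <- contract(st, c(1, 2, 3), triangleGraphlet())
  set.seed(1)
  res2 <- sampleBatch(occ, st2, B = 10)
  expect_length(res2$batch, 1)
  expect_identical(nrow(res2$occurrences[[1]]), 1L)
  expect_identical(unname(res2$batch[[1]]$members), c(4L, 5L, 6L))
  # fixed seed gives identical batches
  set.seed(7); a <- sampleBatch(occ, st, B = 1)
  set.seed(7); b <- sampleBatch(occ, st, B = 1)
  expect_identical(a, b)
})

test_that("model selection is conservative on structureless graphs", {
  g <- randomDigraph(60, 420, 19)
  rep <- selectModel(g, sizes = 3, nRuns = 2, seed = 5)
  expect_length(motifIds(rep), 0)
  expect_gte(rep@deltaLstar, 0)
  expect_true(rep@bestLabel %in% c("ER", "CM", "RER", "RCM"))
  expect_true(is.na(rep@deltaLmotifs))
  # reproducibility of the whole report
  rep2 <- selectModel(g, sizes = 3, nRuns = 2, seed = 5)
  expect_identical(rep@models, rep2@models)
  expect_identical(rep@runCodelengths, rep2@runCodelengths)
})

test_that("model selection recovers planted structure with a motif model", {
  pm <- plantMotifs(60, 220, c("d5-fffff" = 6), seed = 8)
  gamma <- c(enumerateGraphlets(3, 3), list(graphletFromId(clique5Id)))
  census <- subgraphCensus(pm$graph, gamma = gamma, sizes = c(3, 5))
  rep <- selectModel(pm$graph, census = census, nRuns = 2, seed = 9)
  expect_true(grepl("motifs", rep@bestLabel))
  expect_true(clique5Id %in% motifIds(rep))
  expect_false(is.na(rep@deltaLmotifs))
  expect_gt(rep@deltaLmotifs, 0)
  expect_equal(rep@deltaLstar,
               motifFreeCodeLength(pm$graph, "ER") - rep@codelength,
               tolerance = 1e-9)
})

test_that("the no-hypercompression bound is clipped to probabilities", {
  expect_equal(pvalueBound(10), 2^-10)
  expect_equal(pvalueBound(0), 1)
  expect_equal(pvalueBound(-3), 1)
})
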