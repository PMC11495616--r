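# Planted-motif generator and null-model randomizers.

test_that("planted expansion has exactly predictable node and edge counts", {
  placements <- c("d5-fffff" = 3, "d3-19" = 2)
  pm <- plantMotifs(50, 150, placements, seed = 4)
  expect_identical(numNodes(pm$graph), 50L + 3L * 4L + 2L * 2L)
  expect_identical(numEdges(pm$graph), 150L + 3L * 20L + 2L * 3L)
  lat <- plantedLatentParams(300, 0.025, c("d5-fffff" = 20))
  expect_identical(lat$NLatent, 300L - 20L * 4L)
  expect_identical(lat$ELatent, as.integer(round(0.025 * 300 * 299) - 20 * 20))
})

test_that("planted subsets are disjoint and induce their graphlets", {
  pm <- plantMotifs(50, 160, c("d5-fffff" = 4, "d4-fff" = 3), seed = 12)
  members <- lapply(pm$groundTruth, `[[`, "members")
  expect_identical(anyDuplicated(unlist(members)), 0L)
  for (gt in pm$groundTruth) {
    expect_identical(inducedGraphletId(pm$graph, gt$members), gt$graphlet)
  }
})

test_that("randomizers preserve their family's features exactly", {
  g <- randomDigraph(40, 260, 3)
  # give the graph some reciprocity so RER/RCM constraints are nontrivial
  g <- connectomeLikeGraph(N = 40, E = 260, reciprocatedFraction = 0.3, seed = 3)
  H <- asMultigraph(g)
  for (seed in 1:3) {
    er <- randomizeGraph(g, "ER", seed = seed)
    expect_identical(numEdges(er), numEdges(g))
    expect_identical(numNodes(er), numNodes(g))

    cm <- randomizeGraph(g, "CM", seed = seed)
    Hc <- asMultigraph(cm)
    expect_identical(unname(rowSums(Hc@A)), unname(rowSums(H@A)))
    expect_identical(unname(colSums(Hc@A)), unname(colSums(H@A)))

    rer <- randomizeGraph(g, "RER", seed = seed)
    Hr <- asMultigraph(rer)
    expect_identical(reciprocatedEdgeCount(Hr), reciprocatedEdgeCount(H))
    expect_identical(nonReciprocatedEdgeCount(Hr), nonReciprocatedEdgeCount(H))

    rcm <- randomizeGraph(g, "RCM", seed = seed)
    Hm <- asMultigraph(rcm)
    S <- symPart(H); Sm <- symPart(Hm)
    As <- asymPart(H); Asm <- asymPart(Hm)
    expect_identical(unname(rowSums(Sm)), unname(rowSums(S)))     # kappa^m
    expect_identical(unname(rowSums(Asm)), unname(rowSums(As)))   # kappa^+
    expect_identical(unname(colSums(Asm)), unname(colSums(As)))   # kappa^-
  }
})

test_that("degree-preserving swaps stay within the brute-force ensemble", {
  # directed 3-cycle: only two simple digraphs share k+ = k- = (1,1,1)
  cyc <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 1)))
  ensemble <- character()
  for (m in 0:63) {
    e <- mdlmotif:::.edgesFromMask(3L, m)
    A <- adjFromEdges(e, 3)
    if (all(rowSums(A) == 1) && all(colSums(A) == 1))
      ensemble <- c(ensemble, paste(as.vector(A), collapse = ""))
  }
  expect_length(ensemble, 2)
  for (seed in 1:5) {
    r <- suppressWarnings(randomizeGraph(cyc, "CM", seed = seed))
    expect_true(paste(as.vector(adjacencyMatrix(r)), collapse = "") %in% ensemble)
  }
})

test_that("swap chains visit a small ensemble roughly uniformly", {
  # directed 4-cycle: 9 simple digraphs with all in/out degrees one
  cyc4 <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  keys <- character(400)
  for (seed in seq_along(keys)) {
    r <- randomizeGraph(cyc4, "CM", seed = seed)
    keys[seed] <- paste(as.vector(adjacencyMatrix(r)), collapse = "")
  }
  tab <- table(keys)
  expect_identical(length(tab), 9L)
  # Monte-Carlo uniformity: each state within a loose band around 400/9
  expect_true(all(tab > 400 / 9 * 0.4 & tab < 400 / 9 * 2.2))
})

test_that("the synthetic reference graph hits its target summary statistics", {
  g <- connectomeLikeGraph(N = 100, E = 1200, reciprocatedFraction = 0.3, seed = 2)
  expect_identical(numNodes(g), 100L)
  expect_identical(numEdges(g), 1200L)
  H <- asMultigraph(g)
  expect_identical(reciprocatedEdgeCount(H), as.integer(round(0.3 * 1200 / 2)))
  # heavy-tailed propensities give an overdispersed degree sequence
  k <- rowSums(H@A) + colSums(H@A)
  expect_gt(var(k) / mean(k), 2)
})
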