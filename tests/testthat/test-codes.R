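# Codelengths: integer/sequence codes, base entropies, four-part totals.

test_that("universal integer code matches its closed form", {
  expect_equal(integerCodeLength(1), 1)
  expect_equal(integerCodeLength(3), log2(12))
  expect_equal(integerCodeLength(9576), log2(9576 * 9577))
  expect_error(integerCodeLength(0), "positive")
})

test_that("sequence code is permutation-invariant and respects the uniform bound", {
  expect_equal(sequenceCodeLength(c(1, 2, 3)), sequenceCodeLength(c(3, 1, 2)))
  # constant sequence: uniform part is LN(2)+LN(2); total bounded by it
  expect_lte(sequenceCodeLength(c(2, 2, 2, 2)),
             2 * log2(6) + log2(3) + integerCodeLength(4))
  expect_error(sequenceCodeLength(numeric(0)), "nonempty")
  expect_error(sequenceCodeLength(c(1, -1)), "nonnegative")
})

test_that("sequence code equals a straight-from-formula oracle", {
  # independent evaluation of the three candidate codes
  oracle <- function(x) {
    n <- length(x); lo <- min(x); hi <- max(x); K <- hi - lo + 1
    LNf <- function(v) log2(max(v, 1) * (max(v, 1) + 1))
    LU <- n * log2(K) + LNf(hi) + LNf(lo)
    dm <- function(lambda) {
      Lam <- K * lambda
      tot <- lgamma(Lam) - lgamma(n + Lam)
      for (mu in lo:hi) {
        c_mu <- sum(x == mu)
        tot <- tot + lgamma(lambda + c_mu) - lgamma(lambda)
      }
      -tot / log(2)
    }
    min(LU, dm(1), dm(0.5)) + log2(3) + log2(n * (n + 1))
  }
  for (x in list(c(0, 5), c(1, 1, 4, 2), c(0, 0, 0), c(3, 7, 7, 2, 0, 1))) {
    expect_equal(sequenceCodeLength(x), oracle(x), tolerance = 1e-10)
  }
})

test_that("Dirichlet-multinomial candidate approaches the uniform code as lambda grows", {
  x <- c(0, 2, 1, 2, 0, 1, 1)
  n <- length(x); K <- 3
  dm <- function(lambda) {
    Lam <- K * lambda
    tot <- lgamma(Lam) - lgamma(n + Lam)
    for (mu in 0:2) tot <- tot + lgamma(lambda + sum(x == mu)) - lgamma(lambda)
    -tot / log(2)
  }
  expect_equal(dm(1e7), n * log2(K), tolerance = 1e-4)
})

test_that("multigraph base entropies reproduce the worked examples", {
  H <- multigraph(rbind(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)))
  expect_equal(baseEntropy(H, "ER"), 2 * log2(6) - 1, tolerance = 1e-9)
  H2 <- multigraph(rbind(c(0, 2, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_equal(baseEntropy(H2, "ER"), 2 * log2(6), tolerance = 1e-9)
  # degree sequence that admits a single multigraph: zero bits
  H3 <- multigraph(rbind(c(0, 2), c(0, 0)))
  expect_equal(baseEntropy(H3, "CM"), 0, tolerance = 1e-9)
})

test_that("simple-graph entropies match their counting oracles", {
  g <- directedGraph(rbind(c(1, 2), c(2, 3)), N = 3)
  expect_equal(simpleEntropy(g, "ER"), log2(choose(6, 2)), tolerance = 1e-9)
  # oracle: enumerate all simple 3-node digraphs with Em = 1, Ed = 1
  nWith <- 0
  for (m in 0:63) {
    e <- mdlmotif:::.edgesFromMask(3L, m)
    A <- adjFromEdges(e, 3)
    S <- pmin(A, t(A)); As <- pmax(A - t(A), 0)
    if (sum(S[upper.tri(S)]) == 1 && sum(As) == 1) nWith <- nWith + 1
  }
  expect_equal(nWith, 12)
  grer <- directedGraph(rbind(c(1, 2), c(2, 1), c(1, 3)), N = 3)
  expect_equal(simpleEntropy(grer, "RER"), log2(nWith), tolerance = 1e-9)
  # directed path: log2 2 minus the asymptotic correction
  expect_equal(simpleEntropy(g, "CM"), 1 - 1 / (2 * log(2)), tolerance = 1e-9)
})

test_that("Kraft sums pin down the base-code conventions", {
  # all 3-node multigraphs with up to 3 total edges, grouped by features
  compositions <- function(total, k) {
    if (k == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (v in 0:total) out <- rbind(out, cbind(v, compositions(total - v, k - 1)))
    out
  }
  phiKey <- function(A, fam) {
    S <- pmin(A, t(A)); As <- pmax(A - t(A), 0)
    switch(fam,
      ER = paste(sum(A)),
      CM = paste(paste(rowSums(A), collapse = ","), paste(colSums(A), collapse = ","), sep = ";"),
      RER = paste(sum(S[upper.tri(S)]), sum(As)),
      RCM = paste(paste(rowSums(S), collapse = ","), paste(rowSums(As), collapse = ","),
                  paste(colSums(As), collapse = ","), sep = ";"))
  }
  for (E in 1:3) {
    comp <- compositions(E, 6)
    mats <- lapply(seq_len(nrow(comp)), function(r) {
      A <- matrix(0L, 3, 3); A[row(A) != col(A)] <- as.integer(comp[r, ]); A
    })
    for (fam in c("ER", "CM", "RER", "RCM")) {
      keys <- vapply(mats, phiKey, character(1), fam)
      p <- vapply(mats, function(A) 2^(-baseEntropy(multigraph(A), fam)), numeric(1))
      sums <- as.numeric(tapply(p, keys, sum))
      if (fam == "ER") {
        expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
      } else {
        expect_true(all(sums <= 1 + 1e-9))
      }
    }
  }
  # exact simple-graph codes over all 64 labeled 3-node digraphs
  allG <- lapply(0:63, function(m) directedGraph(mdlmotif:::.edgesFromMask(3L, m), N = 3))
  for (fam in c("ER", "RER")) {
    keys <- vapply(allG, function(g) phiKey(adjacencyMatrix(g), fam), character(1))
    p <- vapply(allG, function(g) 2^(-simpleEntropy(g, fam)), numeric(1))
    sums <- as.numeric(tapply(p, keys, sum))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  }
})

test_that("entropy order holds in the contraction regime and exact codes are nonnegative", {
  # RCM <= CM, RCM <= RER, CM <= ER on multigraph views of random simple
  # graphs (the states the optimizer visits)
  for (seed in 1:25) {
    H <- asMultigraph(randomDigraph(25, 100, seed))
    s <- vapply(c("ER", "CM", "RER", "RCM"), function(f) baseEntropy(H, f), numeric(1))
    expect_lte(s[["RCM"]], s[["CM"]] + 1e-9)
    expect_lte(s[["RCM"]], s[["RER"]] + 1e-9)
    expect_lte(s[["CM"]], s[["ER"]] + 1e-9)
    expect_true(all(s >= -1e-9))
    expect_gte(simpleEntropy(randomDigraph(25, 100, seed), "ER"), 0)
  }
})

test_that("model complexity composes the integer and sequence codes", {
  g <- directedGraph(rbind(c(1, 2), c(2, 3)), N = 3)
  expect_equal(modelComplexity(g, "ER"), log2(12) + log2(6), tolerance = 1e-9)
  # zero-capable split stays finite when Ed = 0
  gm <- directedGraph(rbind(c(1, 2), c(2, 1)), N = 2)
  expect_true(is.finite(modelComplexity(gm, "RER")))
  # CM symmetry for the all-ones degree sequence
  cyc <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 1)))
  expect_equal(modelComplexity(cyc, "CM"),
               2 * sequenceCodeLength(c(1, 1, 1)), tolerance = 1e-9)
})

test_that("motif-set and supernode-label codelengths follow their closed forms", {
  expect_equal(motifSetCodeLength(motifSet(), 9576), 0)
  ms <- motifSet(c("d3-19", "d3-19", "d3-3"))
  expect_equal(motifSetCodeLength(ms, 9576),
               2 * log2(9576) + integerCodeLength(9576) + 2 * log2(2) +
                 integerCodeLength(2), tolerance = 1e-9)
  ms1 <- motifSet("d3-19")
  expect_equal(motifSetCodeLength(ms1, 9576),
               log2(9576) + integerCodeLength(9576) + integerCodeLength(1),
               tolerance = 1e-9)
  expect_equal(supernodeLabelCodeLength(5, motifSet(c("d3-19", "d3-19"))),
               log2(10), tolerance = 1e-9)
  expect_equal(supernodeLabelCodeLength(4, motifSet(c("d3-19", "d3-3"))),
               log2(6) + 1, tolerance = 1e-9)
  expect_equal(supernodeLabelCodeLength(7, motifSet()), 0)
  expect_error(supernodeLabelCodeLength(1, motifSet(c("d3-19", "d3-3"))), "more supernodes")
})

test_that("rewiring costs reproduce the worked wiring configurations", {
  # 4-clique supernode with a plain neighbor wired by 2 in- and 2 out-edges
  e <- rbind(cliqueEdges(4), c(5, 1), c(5, 2), c(1, 5), c(2, 5))
  g <- directedGraph(e, N = 5)
  st <- contract(reductionState(g, "ER"), 1:4, graphlet(cliqueEdges(4), 4))
  expect_equal(rewiringCost(st, st@supernodes[[1]]$id), log2(36), tolerance = 1e-9)

  # supernodes of sizes 4 and 5 joined by a single edge: C(20, 1) choices
  e2 <- rbind(cliqueEdges(4), cliqueEdges(5) + 4L, c(1, 5))
  g2 <- directedGraph(e2, N = 9)
  st2 <- contract(reductionState(g2, "ER"), 1:4, graphlet(cliqueEdges(4), 4))
  st2 <- contract(st2, 5:9, graphlet(cliqueEdges(5), 5))
  expect_equal(rewiringCost(st2, st2@supernodes[[1]]$id), log2(20), tolerance = 1e-9)
  expect_equal(rewiringCost(st2, st2@supernodes[[2]]$id), 0, tolerance = 1e-9)
})

test_that("reconstruction codelength matches the triangle worked example", {
  g <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 1), c(3, 5)), N = 5)
  st0 <- reductionState(g, "ER")
  expect_equal(reconstructionCodeLength(st0), 0)
  st <- contract(st0, 1:3, triangleGraphlet())
  expect_equal(reconstructionCodeLength(st),
               log2(factorial(5) / factorial(3)) + 1 + 2 * log2(3),
               tolerance = 1e-9)
})

test_that("total codelength is additive and invariant under relabeling", {
  g <- randomDigraph(15, 45, 2)
  census <- subgraphCensus(g, sizes = 3)
  gi <- which(census@counts > 0)[1]
  members <- occurrenceMatrix(census, gi)[1, ]
  st <- contract(reductionState(g, "CM"), members, census@gamma[[gi]])
  expect_equal(totalCodeLength(st),
               motifSetCodeLength(st@motifs, st@gammaSize) +
                 baseEntropy(st@H, "CM") + modelComplexity(st@H, "CM") +
                 supernodeLabelCodeLength(nrow(st@H@A), st@motifs) +
                 reconstructionCodeLength(st), tolerance = 1e-9)
  # relabeling invariance of the uncontracted total
  set.seed(8)
  sigma <- sample.int(g@N)
  g2 <- directedGraph(cbind(sigma[g@edges[, 1]], sigma[g@edges[, 2]]), N = g@N)
  for (fam in c("ER", "CM", "RER", "RCM")) {
    expect_equal(totalCodeLength(reductionState(g, fam)),
                 totalCodeLength(reductionState(g2, fam)), tolerance = 1e-9)
    expect_equal(motifFreeCodeLength(g, fam), motifFreeCodeLength(g2, fam),
                 tolerance = 1e-9)
  }
  # with an empty motif set the total is the multigraph code of G itself
  st0 <- reductionState(g, "ER")
  expect_equal(totalCodeLength(st0),
               baseEntropy(st0@H, "ER") + modelComplexity(st0@H, "ER"),
               tolerance = 1e-9)
})
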