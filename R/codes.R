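# Codelength computations: universal integer/sequence codes, the eight base
# model entropies (multigraph and simple variants), and the four-part
# codelength of a reduction state. All logarithms are base 2 and
# log-factorials go through lgamma. These R implementations are the naive,
# full-recomputation reference; the greedy engine maintains the same
# quantities incrementally and is validated against them.

.FAMILIES <- c("ER", "CM", "RER", "RCM")

.lf <- function(n) lgamma(n + 1) / log(2)        # log2(n!)
.log2choose <- function(n, r) {
  ifelse(r <= 0 | r >= n, 0,
         (lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)) / log(2))
}
.LNg <- function(n) { m <- pmax(n, 1); log2(m * (m + 1)) }  # zero-guarded L_N

#' Universal integer code length
#'
#' `L_N(n) = log2[n(n+1)]`, the number of bits of a universal code for a
#' positive integer. Call sites where the encoded integer can legitimately be
#' zero (reciprocated/non-reciprocated edge counts, sequence minima) use the
#' guarded value `L_N(max(n, 1))` internally.
#'
#' @param n positive integer.
#' @return Code length in bits.
#' @examples
#' integerCodeLength(1) # 1 bit
#' @export
integerCodeLength <- function(n) {
  if (any(n <= 0)) stop("integer code is defined for positive integers")
  log2(n * (n + 1))
}

#' Universal code length of an integer sequence
#'
#' Minimum over three candidate codes -- a uniform code over the value range
#' and two prequential Dirichlet-multinomial codes with concentration 1 and
#' 1/2 over the integer support `[min(x), max(x)]` -- plus `log2 3` bits for
#' the code identity and the integer code for the length.
#'
#' @param x vector of nonnegative integers.
#' @return Code length in bits.
#' @export
sequenceCodeLength <- function(x) {
  if (length(x) == 0) stop("sequence must be nonempty")
  if (any(x < 0)) stop("sequence entries must be nonnegative")
  n <- length(x)
  lo <- min(x); hi <- max(x)
  K <- hi - lo + 1
  LU <- n * log2(K) + .LNg(hi) + .LNg(lo)
  cnt <- tabulate(x - lo + 1L, nbins = K)
  Ldm <- vapply(c(1, 0.5), function(lambda) {
    Lam <- K * lambda
    (-lgamma(Lam) + lgamma(n + Lam) -
       sum(lgamma(lambda + cnt) - lgamma(lambda))) / log(2)
  }, numeric(1))
  min(LU, Ldm) + log2(3) + integerCodeLength(n)
}

# ---------------------------------------------------------------------------
# feature extraction
# ---------------------------------------------------------------------------

#' Constrained features of a graph under a base model family
#'
#' @param x a [Multigraph-class] or [DirectedGraph-class].
#' @param family one of `"ER"`, `"CM"`, `"RER"`, `"RCM"`.
#' @return A named list of the features the microcanonical family constrains:
#'   `(N, E)` for ER, in-/out-degree sequences for CM, `(N, Em, Ed)` for RER,
#'   and the reciprocal plus non-reciprocated degree sequences for RCM.
#' @export
graphFeatures <- function(x, family = c("ER", "CM", "RER", "RCM")) {
  family <- match.arg(family)
  A <- adjacencyMatrix(x)
  S <- pmin(A, t(A))
  As <- pmax(A - t(A), 0)
  switch(family,
    ER = list(N = nrow(A), E = sum(A)),
    CM = list(kout = rowSums(A), kin = colSums(A)),
    RER = list(N = nrow(A), Em = sum(S[upper.tri(S)]), Ed = sum(As)),
    RCM = list(km = rowSums(S), kp = rowSums(As), kmi = colSums(As)))
}

# ---------------------------------------------------------------------------
# entropies
# ---------------------------------------------------------------------------

#' Multigraph base-model entropy
#'
#' Exact microcanonical entropy (in bits) of a multigraph under one of the
#' four base models. The ER and RER codes count uniform edge throws; the CM
#' and RCM codes are stub-matching codes, whose probability of a multigraph
#' carries the product of multiedge factorials as a divisor. The reading of
#' the factorial terms is pinned down by a Kraft-sum oracle in the test
#' suite: summing `2^-S` over brute-force-enumerable ensembles gives exactly
#' 1 for the ER code and at most 1 for the others.
#'
#' @param H a [Multigraph-class].
#' @param family one of `"ER"`, `"CM"`, `"RER"`, `"RCM"`.
#' @return Entropy in bits.
#' @examples
#' H <- multigraph(rbind(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)))
#' baseEntropy(H, "ER") # 2*log2(6) - 1
#' @export
baseEntropy <- function(H, family = c("ER", "CM", "RER", "RCM")) {
  family <- match.arg(family)
  stopifnot(is(H, "Multigraph"))
  A <- H@A
  N <- nrow(A)
  E <- sum(A)
  off <- A[row(A) != col(A)]
  S <- pmin(A, t(A))
  As <- pmax(A - t(A), 0)
  Em <- sum(S[upper.tri(S)])
  Ed <- sum(As)
  switch(family,
    ER = (if (E > 0) E * log2(N * (N - 1)) else 0) - .lf(E) + sum(.lf(off)),
    CM = {
      kout <- rowSums(A); kin <- colSums(A)
      .lf(E) - sum(.lf(kout) + .lf(kin)) + sum(.lf(off))
    },
    RER = (if (Em + Ed > 0) (Em + Ed) * log2(N * (N - 1)) else 0) -
      (Em + .lf(Em)) - .lf(Ed) +
      sum(.lf(S[upper.tri(S)])) + sum(.lf(As[row(As) != col(As)])),
    RCM = {
      km <- rowSums(S); kp <- rowSums(As); kmi <- colSums(As)
      (.lf(2 * Em) - Em - .lf(Em)) + .lf(Ed) -
        sum(.lf(km) + .lf(kp) + .lf(kmi)) +
        sum(.lf(S[upper.tri(S)])) + sum(.lf(As[row(As) != col(As)]))
    })
}

#' Simple-graph entropy (motif-free reference codes)
#'
#' Entropy of a simple directed graph under the four dyadic models. The ER
#' and RER entropies are exact binomial/multinomial counts; the CM and RCM
#' entropies carry the standard asymptotic correction terms (second-moment
#' ratios over plain node averages), which can make them slightly negative
#' on tiny degenerate graphs.
#'
#' @param g a [DirectedGraph-class].
#' @param family one of `"ER"`, `"CM"`, `"RER"`, `"RCM"`.
#' @return Entropy in bits.
#' @examples
#' g <- directedGraph(rbind(c(1, 2), c(2, 3)), N = 3)
#' simpleEntropy(g, "ER") # log2 choose(6, 2)
#' @export
simpleEntropy <- function(g, family = c("ER", "CM", "RER", "RCM")) {
  family <- match.arg(family)
  stopifnot(is(g, "DirectedGraph"))
  A <- adjacencyMatrix(g)
  N <- nrow(A)
  E <- sum(A)
  S <- pmin(A, t(A))
  As <- pmax(A - t(A), 0)
  Em <- sum(S[upper.tri(S)])
  Ed <- sum(As)
  rat <- function(num, den) if (den == 0) 0 else num / den
  switch(family,
    ER = lchoose(N * (N - 1), E) / log(2),
    RER = {
      P <- N * (N - 1) / 2
      (lgamma(P + 1) - lgamma(P - Em - Ed + 1) - lgamma(Em + 1) -
         lgamma(Ed + 1)) / log(2) + Ed
    },
    CM = {
      kout <- rowSums(A); kin <- colSums(A)
      .lf(E) - sum(.lf(kout) + .lf(kin)) -
        rat(mean(kout^2) * mean(kin^2), mean(kout) * mean(kin)) / (2 * log(2))
    },
    RCM = {
      km <- rowSums(S); kp <- rowSums(As); kmi <- colSums(As)
      corr <- 0.5 * rat(mean(km^2), mean(km))^2 +
        rat(mean(kp^2) * mean(kmi^2), mean(kp) * mean(kmi)) +
        rat(mean(kp * kmi)^2, mean(kp) * mean(kmi)) +
        rat(mean(km * kp) * mean(km * kmi), mean(km) * mean(kp))
      (Em + .lf(Em)) - sum(.lf(km)) + .lf(Ed) - sum(.lf(kp) + .lf(kmi)) -
        corr / (2 * log(2))
    })
}

#' Parametric model complexity
#'
#' Bits needed to encode the constrained features of a base model; identical
#' for the multigraph and simple-graph variants. Scalar counts use the
#' universal integer code (zero-guarded for the reciprocity split), degree
#' sequences the universal sequence code.
#'
#' @param x a [Multigraph-class], [DirectedGraph-class], or a feature list as
#'   returned by [graphFeatures()].
#' @param family one of `"ER"`, `"CM"`, `"RER"`, `"RCM"`.
#' @return Complexity in bits.
#' @export
modelComplexity <- function(x, family = c("ER", "CM", "RER", "RCM")) {
  family <- match.arg(family)
  phi <- if (is.list(x)) x else graphFeatures(x, family)
  switch(family,
    ER = .LNg(phi$N) + .LNg(phi$E),
    CM = sequenceCodeLength(phi$kout) + sequenceCodeLength(phi$kin),
    RER = .LNg(phi$N) + .LNg(phi$Em) + .LNg(phi$Ed),
    RCM = sequenceCodeLength(phi$km) + sequenceCodeLength(phi$kp) +
      sequenceCodeLength(phi$kmi))
}

# ---------------------------------------------------------------------------
# motif-set terms
# ---------------------------------------------------------------------------

#' Codelength of the motif multiset
#'
#' Identity of each distinct motif (`log2 |Gamma|` bits each), the dictionary
#' size, the per-motif repetition counts (`log2 m_max` bits each) and the
#' maximal repetition count. An empty motif set costs nothing, which makes
#' the uncontracted state of the optimizer well defined.
#'
#' @param ms a [MotifSet-class].
#' @param gammaSize dictionary size `|Gamma|`.
#' @return Code length in bits.
#' @export
motifSetCodeLength <- function(ms, gammaSize) {
  stopifnot(gammaSize >= 1)
  m <- multiplicities(ms)
  if (length(m) == 0) return(0)
  mmax <- max(m)
  length(m) * log2(gammaSize) + integerCodeLength(gammaSize) +
    length(m) * log2(mmax) + integerCodeLength(mmax)
}

#' Codelength for labeling the supernodes of H
#'
#' Which of the `N(H)` nodes are supernodes, and which graphlet each one
#' carries (the distinguishable orderings of the motif multiset).
#'
#' @param NH node count of the reduced multigraph.
#' @param ms a [MotifSet-class].
#' @return Code length in bits.
#' @export
supernodeLabelCodeLength <- function(NH, ms) {
  m <- multiplicities(ms)
  s <- length(ms)
  if (s > NH) stop("more supernodes than nodes in H")
  if (s == 0) return(0)
  .log2choose(NH, s) + (.lf(s) - sum(.lf(m)))
}

#' Rewiring cost of one supernode
#'
#' Bits needed to specify how the multiedges incident to a supernode attach
#' to the internal nodes of the subgraph it replaces: binomial choices of
#' distinct internal endpoints towards plain neighbors (both directions) and
#' of distinct internal node pairs towards supernode neighbors (outgoing
#' edges only; incoming ones are charged to the other supernode).
#'
#' @param state a [ReductionState-class].
#' @param id supernode id (as recorded in `state@supernodes`).
#' @return Code length in bits.
#' @export
rewiringCost <- function(state, id) {
  idx <- match(id, state@nodeIds)
  info <- Find(function(s) s$id == id, state@supernodes)
  if (is.null(info) || is.na(idx)) stop("not a supernode of this state: ", id)
  ns <- length(info$members)
  A <- state@H@A
  superIds <- vapply(state@supernodes, `[[`, integer(1), "id")
  sizes <- vapply(state@supernodes, function(s) length(s$members), integer(1))
  total <- 0
  for (j in seq_len(nrow(A))) {
    if (j == idx) next
    jid <- state@nodeIds[j]
    sj <- match(jid, superIds)
    if (is.na(sj)) {
      if (A[idx, j] > ns || A[j, idx] > ns)
        stop("multiplicity exceeds rewiring capacity")
      total <- total + .log2choose(ns, A[idx, j]) + .log2choose(ns, A[j, idx])
    } else {
      cap <- ns * sizes[sj]
      if (A[idx, j] > cap) stop("multiplicity exceeds rewiring capacity")
      total <- total + .log2choose(cap, A[idx, j])
    }
  }
  total
}

#' Reconstruction codelength
#'
#' Bits needed to recover the original labeled graph from the reduced
#' multigraph: the original node labeling, one orientation per contracted
#' subgraph (`log2 n!/|Aut|` bits), and the rewiring of every supernode.
#'
#' @param state a [ReductionState-class].
#' @return Code length in bits.
#' @export
reconstructionCodeLength <- function(state) {
  NG <- state@G@N
  NH <- nrow(state@H@A)
  orient <- sum(vapply(state@supernodes,
                       function(s) log2(s$graphlet@orientations), numeric(1)))
  rew <- sum(vapply(state@supernodes,
                    function(s) rewiringCost(state, s$id), numeric(1)))
  (.lf(NG) - .lf(NH)) + orient + rew
}

#' Total codelength of a reduction state
#'
#' The four-part description length: the motif multiset, the reduced
#' multigraph under the base code (entropy plus parametric complexity), the
#' supernode labeling, and the reconstruction information.
#'
#' @param state a [ReductionState-class].
#' @return Code length in bits.
#' @export
totalCodeLength <- function(state) {
  motifSetCodeLength(state@motifs, state@gammaSize) +
    baseEntropy(state@H, state@base) +
    modelComplexity(state@H, state@base) +
    supernodeLabelCodeLength(nrow(state@H@A), state@motifs) +
    reconstructionCodeLength(state)
}

#' Motif-free reference codelength of a simple graph
#'
#' The purely dyadic description of the observed graph: simple-graph entropy
#' plus parametric complexity under the given family. These references enter
#' model selection alongside the motif-based codes and keep the inference
#' conservative on structureless graphs.
#'
#' @param g a [DirectedGraph-class].
#' @param family one of `"ER"`, `"CM"`, `"RER"`, `"RCM"`.
#' @return Code length in bits.
#' @export
motifFreeCodeLength <- function(g, family = c("ER", "CM", "RER", "RCM")) {
  family <- match.arg(family)
  simpleEntropy(g, family) + modelComplexity(g, family)
}
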