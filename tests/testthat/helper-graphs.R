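# Shared fixtures and independent oracles for the test suite.

# uniform simple digraph with exactly E edges
randomDigraph <- function(N, E, seed) {
  directedGraph(mdlmotif:::.er_resample_cpp(N, E, as.integer(seed)) + 1L, N = N)
}

# complete digraph on n nodes
cliqueEdges <- function(n) {
  eg <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  eg[eg[, 1] != eg[, 2], c(1, 2), drop = FALSE]
}

triangleGraphlet <- function() graphlet(rbind(c(1, 2), c(2, 3), c(3, 1)), 3)
clique5Id <- "d5-fffff"

# pure-R permutation isomorphism oracle, independent of the C++ path
permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

adjFromEdges <- function(edges, n) {
  A <- matrix(0L, n, n)
  if (length(edges) && nrow(edges)) A[as.matrix(edges)] <- 1L
  A
}

isoOracle <- function(e1, e2, n) {
  A <- adjFromEdges(e1, n); B <- adjFromEdges(e2, n)
  if (sum(A) != sum(B)) return(FALSE)
  for (p in seq_len(nrow(permutations(n)))) {
    sigma <- permutations(n)[p, ]
    if (identical(A[sigma, sigma], B)) return(TRUE)
  }
  FALSE
}

# brute-force census oracle: scan every node subset of size k
bruteCensusCounts <- function(g, k) {
  A <- adjacencyMatrix(g)
  counts <- new.env(parent = emptyenv())
  subs <- utils::combn(g@N, k)
  for (ci in seq_len(ncol(subs))) {
    v <- subs[, ci]
    a <- A[v, v, drop = FALSE]
    edges <- which(a == 1L, arr.ind = TRUE)
    if (!isWeaklyConnected(edges, k)) next
    id <- graphlet(edges, k)@id
    counts[[id]] <- (if (is.null(counts[[id]])) 0 else counts[[id]]) + 1
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

inducedGraphletId <- function(g, members) {
  A <- adjacencyMatrix(g)
  a <- A[members, members, drop = FALSE]
  graphlet(which(a == 1L, arr.ind = TRUE), length(members))@id
}
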