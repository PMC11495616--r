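# Core graph types, canonical forms, automorphisms and connectivity.

#' Construct a simple directed graph
#'
#' @param edges two-column matrix (or data.frame) of directed edges. Columns
#'   may contain integer node ids or arbitrary labels; labels are mapped to
#'   dense 1-based integer ids in first-appearance order.
#' @param N optional node count; defaults to the number of distinct labels
#'   (isolated nodes can be included by passing a larger `N` with integer
#'   input).
#' @param labels optional character vector of node labels.
#'
#' @return A [DirectedGraph-class] object.
#' @examples
#' g <- directedGraph(rbind(c("a", "b"), c("b", "a"), c("b", "c")))
#' numNodes(g); numEdges(g)
#' @export
directedGraph <- function(edges, N = NULL, labels = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  if (nrow(edges) > 0 && (is.character(edges) || is.factor(edges))) {
    labs <- unique(as.vector(t(edges)))
    from <- match(edges[, 1], labs)
    to <- match(edges[, 2], labs)
    edges <- cbind(from, to)
    if (is.null(labels)) labels <- labs
  } else {
    storage.mode(edges) <- "integer"
  }
  if (is.null(N)) N <- if (nrow(edges) > 0) max(edges) else 0L
  N <- as.integer(N)
  if (is.null(labels)) labels <- as.character(seq_len(N))
  em <- matrix(as.integer(edges), ncol = 2)
  colnames(em) <- c("from", "to")
  new("DirectedGraph", N = N, edges = em, labels = labels)
}

#' @rdname DirectedGraph-class
#' @export
setMethod("numNodes", "DirectedGraph", function(x) x@N)

#' @rdname DirectedGraph-class
#' @export
setMethod("numEdges", "DirectedGraph", function(x) nrow(x@edges))

#' @rdname DirectedGraph-class
#' @export
setMethod("edgeDensity", "DirectedGraph", function(x) {
  if (x@N < 2) return(0)
  nrow(x@edges) / (x@N * (x@N - 1))
})

#' @rdname DirectedGraph-class
#' @export
setMethod("nodeLabels", "DirectedGraph", function(x) x@labels)

#' @rdname DirectedGraph-class
#' @export
setMethod("adjacencyMatrix", "DirectedGraph", function(x) {
  A <- matrix(0L, x@N, x@N)
  if (nrow(x@edges) > 0) A[x@edges] <- 1L
  A
})

setMethod("show", "DirectedGraph", function(object) {
  cat(sprintf("DirectedGraph with %d nodes, %d edges (density %.4f)\n",
              object@N, nrow(object@edges), edgeDensity(object)))
})

#' Construct a directed multigraph
#'
#' @param A square integer matrix of edge multiplicities (zero diagonal).
#' @return A [Multigraph-class] object.
#' @export
multigraph <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "integer"
  new("Multigraph", A = A)
}

#' Multigraph view of a simple graph
#'
#' @param g a [DirectedGraph-class].
#' @return A [Multigraph-class] with boolean multiplicities.
#' @export
asMultigraph <- function(g) multigraph(adjacencyMatrix(g))

#' @rdname Multigraph-class
#' @export
setMethod("numNodes", "Multigraph", function(x) nrow(x@A))

#' @rdname Multigraph-class
#' @export
setMethod("numEdges", "Multigraph", function(x) sum(x@A))

#' @rdname Multigraph-class
#' @export
setMethod("adjacencyMatrix", "Multigraph", function(x) x@A)

#' @rdname Multigraph-class
#' @export
setMethod("outDegrees", "Multigraph", function(x) rowSums(x@A))

#' @rdname Multigraph-class
#' @export
setMethod("inDegrees", "Multigraph", function(x) colSums(x@A))

#' @rdname Multigraph-class
#' @export
setMethod("symPart", "Multigraph", function(x) pmin(x@A, t(x@A)))

#' @rdname Multigraph-class
#' @export
setMethod("asymPart", "Multigraph", function(x) {
  d <- x@A - t(x@A)
  d[d < 0L] <- 0L
  d
})

#' @rdname Multigraph-class
#' @export
setMethod("reciprocatedEdgeCount", "Multigraph", function(x) {
  S <- symPart(x)
  sum(S[upper.tri(S)])
})

#' @rdname Multigraph-class
#' @export
setMethod("nonReciprocatedEdgeCount", "Multigraph", function(x) sum(asymPart(x)))

setMethod("show", "Multigraph", function(object) {
  cat(sprintf("Multigraph with %d nodes, %d edges (%d reciprocated, %d single)\n",
              nrow(object@A), sum(object@A),
              reciprocatedEdgeCount(object), nonReciprocatedEdgeCount(object)))
})

# ---------------------------------------------------------------------------
# adjacency masks for small digraphs
# ---------------------------------------------------------------------------

# bit position (0-based) of ordered pair (i, j), 1-based node indices
.pairBit <- function(i, j, n) (i - 1L) * (n - 1L) + ifelse(j < i, j - 1L, j - 2L)

#' @noRd
.maskFromEdges <- function(n, edges) {
  if (length(edges) == 0 || nrow(edges) == 0) return(0L)
  edges <- as.matrix(edges)
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed in graphlets")
  bits <- .pairBit(edges[, 1], edges[, 2], n)
  if (anyDuplicated(bits) > 0) stop("duplicate edges in graphlet")
  as.integer(sum(2^bits))
}

#' @noRd
.edgesFromMask <- function(n, mask) {
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (bitwAnd(mask, bitwShiftL(1L, .pairBit(i, j, n))) != 0L)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

#' Canonical form of a small digraph
#'
#' Computes the canonical adjacency mask of a digraph on at most six nodes by
#' brute force over all node permutations: the canonical form is the
#' numerically smallest mask, and two digraphs are isomorphic exactly when
#' their canonical masks coincide.
#'
#' @param edges two-column integer matrix of directed edges on nodes
#'   `1..n`.
#' @param n number of nodes.
#' @return A list with `mask` (canonical integer mask), `perm` (one
#'   permutation achieving it, as a function of old index), and `bits` (the
#'   canonical adjacency bitstring, row-major over ordered pairs).
#' @examples
#' canonicalForm(rbind(c(1, 2), c(2, 3), c(3, 1)), 3)$bits
#' @export
canonicalForm <- function(edges, n) {
  n <- as.integer(n)
  if (n > 6) stop("canonical form supports at most 6 nodes")
  res <- .canonical_mask_cpp(n, .maskFromEdges(n, edges))
  L <- n * (n - 1L)
  bits <- paste(ifelse(bitwAnd(res$mask, bitwShiftL(1L, seq_len(L) - 1L)) != 0L, "1", "0"),
                collapse = "")
  list(mask = res$mask, perm = res$perm + 1L, bits = bits)
}

#' Automorphism group size of a small digraph
#'
#' Counts, by brute force over all `n!` node permutations, the permutations
#' mapping the digraph onto itself.
#'
#' @inheritParams canonicalForm
#' @return Integer, the size of the automorphism group.
#' @examples
#' automorphismCount(rbind(c(1, 2), c(2, 3), c(3, 1)), 3) # directed 3-cycle: 3
#' @export
automorphismCount <- function(edges, n) {
  n <- as.integer(n)
  if (n > 6) stop("automorphism count supports at most 6 nodes")
  .canonical_mask_cpp(n, .maskFromEdges(n, edges))$aut
}

#' Number of distinguishable orientations of a graphlet
#'
#' `n!/|Aut|`: the number of distinct labeled versions of a graphlet on a
#' fixed node set, used both in the reconstruction code and in the
#' planted-motif expander.
#'
#' @inheritParams canonicalForm
#' @return Numeric, `n!` divided by the automorphism count.
#' @export
orientationCount <- function(edges, n) {
  factorial(as.integer(n)) / automorphismCount(edges, n)
}

#' Weak connectivity of a digraph
#'
#' A digraph is weakly connected when the undirected graph obtained by
#' dropping edge directions is connected. A single node is connected.
#'
#' @inheritParams canonicalForm
#' @return Logical.
#' @export
isWeaklyConnected <- function(edges, n) {
  n <- as.integer(n)
  if (n < 1) stop("empty node set")
  if (n <= 6) return(.weakly_connected_mask_cpp(n, .maskFromEdges(n, edges)))
  # union-find for larger node sets
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (length(edges) > 0) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

# ---------------------------------------------------------------------------
# Graphlet objects
# ---------------------------------------------------------------------------

#' @noRd
.graphletFromMask <- function(n, mask, canonicalize = TRUE) {
  res <- .canonical_mask_cpp(n, mask)
  mask <- if (canonicalize) res$mask else mask
  new("Graphlet", n = as.integer(n), mask = as.integer(mask),
      id = sprintf("d%d-%s", n, format(as.hexmode(mask))),
      aut = as.integer(res$aut),
      orientations = factorial(n) / res$aut)
}

#' Construct a graphlet from an edge list
#'
#' Canonicalizes the given small digraph and returns its isomorphism class.
#'
#' @inheritParams canonicalForm
#' @return A [Graphlet-class].
#' @examples
#' graphlet(rbind(c(1, 2), c(2, 1)), 2) # reciprocal dyad
#' @export
graphlet <- function(edges, n) {
  n <- as.integer(n)
  if (n < 1 || n > 5) stop("graphlets support 1 to 5 nodes")
  mask <- .maskFromEdges(n, edges)
  if (!.weakly_connected_mask_cpp(n, mask))
    stop("graphlets must be weakly connected")
  .graphletFromMask(n, mask)
}

#' Parse a graphlet id back into a graphlet
#'
#' @param id character id of the form `"d<n>-<hex mask>"`.
#' @return A [Graphlet-class].
#' @export
graphletFromId <- function(id) {
  m <- regmatches(id, regexec("^d([0-9])-([0-9a-f]+)$", id))[[1]]
  if (length(m) != 3) stop("malformed graphlet id: ", id)
  n <- as.integer(m[2])
  mask <- strtoi(m[3], base = 16L)
  .graphletFromMask(n, mask)
}

#' Render a graphlet as an edge list
#'
#' Returns the edge list of the canonical representative, so reported motif
#' ids can be turned back into concrete circuits.
#'
#' @param g a [Graphlet-class] or a graphlet id string.
#' @return Two-column integer matrix of directed edges on nodes `1..n`.
#' @examples
#' graphletEdges("d3-14")
#' @export
graphletEdges <- function(g) {
  if (is.character(g)) g <- graphletFromId(g)
  .edgesFromMask(g@n, g@mask)
}

#' @rdname Graphlet-class
#' @param x a [Graphlet-class].
#' @export
setMethod("numNodes", "Graphlet", function(x) x@n)

#' @rdname Graphlet-class
#' @export
setMethod("numEdges", "Graphlet", function(x) nrow(graphletEdges(x)))

setMethod("show", "Graphlet", function(object) {
  cat(sprintf("Graphlet %s: %d nodes, %d edges, |Aut| = %d, %g orientations\n",
              object@id, object@n, numEdges(object), object@aut,
              object@orientations))
})

# ---------------------------------------------------------------------------
# MotifSet
# ---------------------------------------------------------------------------

#' Construct a motif multiset
#'
#' @param ids character vector of graphlet ids (with repetition).
#' @return A [MotifSet-class].
#' @export
motifSet <- function(ids = character()) new("MotifSet", ids = as.character(ids))

#' @rdname MotifSet-class
#' @export
setMethod("motifIds", "MotifSet", function(x) x@ids)

#' @rdname MotifSet-class
#' @export
setMethod("multiplicities", "MotifSet", function(x) {
  if (length(x@ids) == 0) return(integer())
  tab <- table(x@ids)
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname MotifSet-class
#' @export
setMethod("length", "MotifSet", function(x) length(x@ids))

setMethod("show", "MotifSet", function(object) {
  if (length(object@ids) == 0) {
    cat("Empty MotifSet\n")
  } else {
    m <- multiplicities(object)
    cat(sprintf("MotifSet with %d occurrences of %d distinct graphlets:\n",
                length(object@ids), length(m)))
    for (id in names(m)) cat(sprintf("  %s x %d\n", id, m[[id]]))
  }
})
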