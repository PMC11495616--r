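# Reduction states and subgraph contraction (reference implementation).

#' Create a fresh reduction state
#'
#' The uncontracted state: `H` is the multigraph view of `G`, there are no
#' supernodes and the motif multiset is empty.
#'
#' @param g a [DirectedGraph-class].
#' @param base base model family, one of `"ER"`, `"CM"`, `"RER"`, `"RCM"`.
#' @param gammaSize dictionary size used in the motif-set code (defaults to
#'   the number of weakly connected 3-5-node graphlet classes).
#' @return A [ReductionState-class].
#' @export
reductionState <- function(g, base = "ER", gammaSize = NULL) {
  stopifnot(is(g, "DirectedGraph"))
  if (is.null(gammaSize)) gammaSize <- length(enumerateGraphlets(3, 5))
  new("ReductionState", G = g, H = asMultigraph(g), nodeIds = seq_len(g@N),
      supernodes = list(), motifs = motifSet(), base = base,
      gammaSize = as.numeric(gammaSize))
}

#' Does a node subset avoid all existing supernodes?
#'
#' @param state a [ReductionState-class].
#' @param members integer vector of original node ids.
#' @return `TRUE` when every member is still a plain node of `H`.
#' @export
nonOverlapping <- function(state, members) {
  all(members %in% state@nodeIds[state@nodeIds <= state@G@N])
}

#' Contract an induced subgraph into a supernode
#'
#' Removes the subset's nodes and internal edges from `H`, replaces them by a
#' single supernode, and redirects every external edge to it; edges of
#' members sharing an external neighbor merge into parallel multiedges. The
#' motif multiset gains the subgraph's graphlet.
#'
#' @param state a [ReductionState-class].
#' @param members integer vector of original node ids whose induced subgraph
#'   in `G` is isomorphic to `graphlet`.
#' @param graphlet a [Graphlet-class] (or graphlet id string).
#' @return The new [ReductionState-class]; the input state is unchanged.
#' @export
contract <- function(state, members, graphlet) {
  if (is.character(graphlet)) graphlet <- graphletFromId(graphlet)
  members <- sort(as.integer(members))
  k <- length(members)
  if (k != graphlet@n) stop("subset size does not match graphlet size")
  if (!nonOverlapping(state, members))
    stop("subset overlaps an existing supernode")
  # isomorphism check against the claimed graphlet
  gEdges <- state@G@edges
  sel <- gEdges[, 1] %in% members & gEdges[, 2] %in% members
  indEdges <- cbind(match(gEdges[sel, 1], members), match(gEdges[sel, 2], members))
  mask <- .canonical_mask_cpp(k, .maskFromEdges(k, indEdges))$mask
  if (mask != graphlet@mask)
    stop("induced subgraph is not isomorphic to ", graphlet@id)

  A <- state@H@A
  idx <- match(members, state@nodeIds)
  keep <- setdiff(seq_len(nrow(A)), idx)
  newRow <- colSums(A[idx, keep, drop = FALSE])   # A_{s, l}
  newCol <- rowSums(A[keep, idx, drop = FALSE])   # A_{l, s}
  A2 <- rbind(cbind(A[keep, keep, drop = FALSE], newCol),
              c(newRow, 0L))
  storage.mode(A2) <- "integer"
  dimnames(A2) <- NULL
  newId <- max(state@G@N, state@nodeIds) + 1L
  sn <- c(state@supernodes,
          list(list(id = newId, graphlet = graphlet, members = members)))
  new("ReductionState", G = state@G, H = multigraph(A2),
      nodeIds = c(state@nodeIds[keep], newId), supernodes = sn,
      motifs = motifSet(c(state@motifs@ids, graphlet@id)),
      base = state@base, gammaSize = state@gammaSize)
}

#' Codelength gain of a putative contraction
#'
#' `L(state) - L(state after contracting the subset)`, by full recomputation
#' of both total codelengths; may be negative and leaves the input state
#' untouched. The greedy engine computes the same quantity incrementally.
#'
#' @inheritParams contract
#' @return Gain in bits.
#' @export
contractionGain <- function(state, members, graphlet) {
  totalCodeLength(state) - totalCodeLength(contract(state, members, graphlet))
}

setMethod("show", "ReductionState", function(object) {
  cat(sprintf("ReductionState (%s base): N(G) = %d -> N(H) = %d, %d supernodes\n",
              object@base, object@G@N, nrow(object@H@A),
              length(object@supernodes)))
})
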