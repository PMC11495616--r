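# S4 containers for graphs, graphlets, census tables and reduction states.

#' Simple directed graph
#'
#' An immutable simple directed graph without self-loops. Nodes are dense
#' 1-based integer ids; the original input labels are kept in `labels`.
#'
#' @slot N integer, number of nodes.
#' @slot edges integer matrix with two columns (from, to), one row per
#'   directed edge; no duplicates, no self-loops.
#' @slot labels character vector of length `N` with the original node labels.
#' @export
setClass("DirectedGraph",
  representation(N = "integer", edges = "matrix", labels = "character"),
  validity = function(object) {
    msg <- character()
    e <- object@edges
    if (ncol(e) != 2) msg <- c(msg, "edges must have two columns")
    if (nrow(e) > 0) {
      if (any(e < 1L) || any(e > object@N)) msg <- c(msg, "edge endpoint out of range")
      if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops are not allowed")
      if (anyDuplicated(e[, 1] * (object@N + 1) + e[, 2]) > 0)
        msg <- c(msg, "duplicate edges are not allowed")
    }
    if (length(object@labels) != object@N) msg <- c(msg, "labels must have length N")
    if (length(msg)) msg else TRUE
  })

#' Integer multigraph
#'
#' A directed multigraph held as a dense integer multiplicity matrix with a
#' zero diagonal. Used for the reduced latent graph produced by subgraph
#' contractions.
#'
#' @slot A integer matrix of edge multiplicities, `A[i, j]` counting parallel
#'   edges from node `i` to node `j`; diagonal zero.
#' @export
setClass("Multigraph",
  representation(A = "matrix"),
  validity = function(object) {
    A <- object@A
    msg <- character()
    if (nrow(A) != ncol(A)) msg <- c(msg, "A must be square")
    if (any(A < 0)) msg <- c(msg, "multiplicities must be nonnegative")
    if (nrow(A) > 0 && any(diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(A != round(A))) msg <- c(msg, "multiplicities must be integers")
    if (length(msg)) msg else TRUE
  })

#' Directed graphlet (isomorphism class)
#'
#' The canonical form of a weakly connected digraph on up to five nodes.
#' The adjacency of the class representative is packed into an integer mask
#' with the ordered pair (i, j) at bit `(i-1)*(n-1) + (j<i ? j : j-1)`
#' (0-based bit positions); the canonical mask is the numeric minimum over
#' all node permutations.
#'
#' @slot n integer, number of nodes.
#' @slot mask integer, canonical adjacency mask.
#' @slot id character, serialized id of the form `"d<n>-<hex mask>"`.
#' @slot aut integer, size of the automorphism group.
#' @slot orientations numeric, `n!/aut`, the number of distinguishable
#'   orientations of the graphlet.
#' @export
setClass("Graphlet",
  representation(n = "integer", mask = "integer", id = "character",
                 aut = "integer", orientations = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@n < 1 || object@n > 6) msg <- c(msg, "graphlet size must be 1..6")
    if (object@aut < 1) msg <- c(msg, "automorphism count must be >= 1")
    if (abs(object@orientations * object@aut - factorial(object@n)) > 1e-6)
      msg <- c(msg, "orientations * aut must equal n!")
    if (length(msg)) msg else TRUE
  })

#' Graphlet census table
#'
#' The graphlet dictionary together with the occurrence lists of the
#' exhaustive induced-subgraph census of a graph. Occurrences are stored per
#' graphlet as a flattened integer vector of sorted node subsets
#' (`n` consecutive entries per occurrence); [occurrenceMatrix()] unpacks
#' them.
#'
#' @slot gamma list of [Graphlet-class] objects (the dictionary, ordered by
#'   size then canonical mask).
#' @slot counts numeric vector of occurrence counts per graphlet.
#' @slot subsets list of flattened occurrence subsets per graphlet (empty
#'   when the census was run in counts-only mode).
#' @slot sizes integer vector of censused subgraph sizes.
#' @slot hasSubsets logical, whether subsets were stored.
#' @export
setClass("GraphletCensus",
  representation(gamma = "list", counts = "numeric", subsets = "list",
                 sizes = "integer", hasSubsets = "logical"))

#' Motif multiset
#'
#' A multiset of graphlet ids: the graphlets contracted so far, with
#' repetition.
#'
#' @slot ids character vector of graphlet ids, one entry per contraction.
#' @export
setClass("MotifSet", representation(ids = "character"))

#' Reduction state
#'
#' The full model state linking the observed graph to its reduced multigraph:
#' the immutable input graph, the current multigraph `H`, the supernodes with
#' their member nodes and graphlets, the motif multiset, and the base code.
#' Node ids of `H` are tracked in `nodeIds`: original nodes keep their id,
#' supernodes receive fresh ids above `N(G)`.
#'
#' @slot G a [DirectedGraph-class].
#' @slot H a [Multigraph-class] over the alive nodes.
#' @slot nodeIds integer vector mapping rows of `H@A` to node ids.
#' @slot supernodes list; each element a list with `id`, `graphlet`
#'   (a [Graphlet-class]) and `members` (original node ids).
#' @slot motifs a [MotifSet-class].
#' @slot base character, one of `"ER"`, `"CM"`, `"RER"`, `"RCM"`.
#' @slot gammaSize numeric, the dictionary size used in the motif-set code.
#' @export
setClass("ReductionState",
  representation(G = "DirectedGraph", H = "Multigraph", nodeIds = "integer",
                 supernodes = "list", motifs = "MotifSet", base = "character",
                 gammaSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@base %in% c("ER", "CM", "RER", "RCM"))
      msg <- c(msg, "base must be one of ER, CM, RER, RCM")
    members <- unlist(lapply(object@supernodes, `[[`, "members"))
    if (anyDuplicated(members) > 0)
      msg <- c(msg, "supernode member sets must be disjoint")
    nExpected <- object@G@N - sum(vapply(object@supernodes,
      function(s) length(s$members) - 1L, integer(1)))
    if (nrow(object@H@A) != nExpected)
      msg <- c(msg, "node count of H inconsistent with contractions")
    if (length(msg)) msg else TRUE
  })

#' Result of one greedy run
#'
#' @slot trajectory numeric, total codelength after each iteration
#'   (element 1 is the uncontracted state).
#' @slot bestIteration integer, 0-based index of the codelength minimum along
#'   the trajectory.
#' @slot state the [ReductionState-class] at the best iteration.
#' @slot contractions list of accepted contractions (graphlet id, members,
#'   gain), in order.
#' @slot base character, base model family.
#' @slot seed integer seed used for the run.
#' @export
setClass("RunResult",
  representation(trajectory = "numeric", bestIteration = "integer",
                 state = "ReductionState", contractions = "list",
                 base = "character", seed = "integer"))

#' Cross-model selection report
#'
#' @slot models data.frame with one row per base family: the motif-free
#'   simple-graph reference codelength and the best motif-based codelength.
#' @slot best the winning [RunResult-class] (or `NULL`-like empty list slot
#'   when a motif-free model wins).
#' @slot bestLabel character, e.g. `"RCM"` or `"CM+motifs"`.
#' @slot codelength numeric, codelength of the selected model.
#' @slot deltaLstar numeric, compressibility relative to the simple
#'   Erdos-Renyi code.
#' @slot deltaLmotifs numeric, best motif-free minus best motif-based
#'   codelength (NA when no motif model wins).
#' @slot pBound numeric, no-hypercompression p-value bound `2^-deltaLstar`.
#' @slot runCodelengths list of numeric vectors, per-family best codelengths
#'   of every greedy run.
#' @slot motifs a [MotifSet-class] (empty when a motif-free model wins).
#' @export
setClass("SelectionReport",
  representation(models = "data.frame", best = "list", bestLabel = "character",
                 codelength = "numeric", deltaLstar = "numeric",
                 deltaLmotifs = "numeric", pBound = "numeric",
                 runCodelengths = "list", motifs = "MotifSet"))

#' Hypothesis-testing baseline result
#'
#' @slot table data.frame with per-graphlet observed counts, null mean and
#'   standard deviation, z-score, raw and Bonferroni-corrected p-values and
#'   the motif flag.
#' @slot settings list echoing the null family, number of null samples,
#'   significance threshold and dictionary size.
#' @export
setClass("HTResult", representation(table = "data.frame", settings = "list"))

#' Topological summary of a motif set
#'
#' @slot perGraphlet data.frame of density, reciprocity and cycle count per
#'   distinct graphlet, with multiplicities.
#' @slot means named numeric vector of multiset-weighted means.
#' @slot baselines named numeric vector of fixed-density random baselines.
#' @export
setClass("MotifSummary",
  representation(perGraphlet = "data.frame", means = "numeric",
                 baselines = "numeric"))
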