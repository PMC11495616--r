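# Graphlet dictionary enumeration and the exhaustive subgraph census.

.dictCache <- new.env(parent = emptyenv())

#' Enumerate the graphlet dictionary
#'
#' Lists all isomorphism classes of weakly connected digraphs (no self-loops)
#' with `nMin` to `nMax` nodes, in deterministic order (size, then canonical
#' mask). Enumeration is by brute force over all labeled digraphs per size
#' with orbit marking, and is cached per size within a session.
#'
#' @param nMin,nMax smallest and largest graphlet size, between 2 and 5.
#' @return A list of [Graphlet-class] objects.
#' @examples
#' length(enumerateGraphlets(3, 3)) # 13 weakly connected 3-node digraphs
#' @export
enumerateGraphlets <- function(nMin = 3, nMax = 5) {
  nMin <- as.integer(nMin); nMax <- as.integer(nMax)
  if (nMin < 2 || nMax > 5 || nMin > nMax)
    stop("graphlet sizes must satisfy 2 <= nMin <= nMax <= 5")
  out <- list()
  for (n in nMin:nMax) {
    key <- as.character(n)
    if (is.null(.dictCache[[key]])) {
      res <- .enumerate_graphlets_cpp(n)
      ord <- order(res$mask)
      .dictCache[[key]] <- lapply(ord, function(i) {
        new("Graphlet", n = n, mask = as.integer(res$mask[i]),
            id = sprintf("d%d-%s", n, format(as.hexmode(res$mask[i]))),
            aut = as.integer(res$aut[i]),
            orientations = factorial(n) / res$aut[i])
      })
    }
    out <- c(out, .dictCache[[key]])
  }
  out
}

#' @noRd
.gammaIds <- function(gamma) vapply(gamma, slot, character(1), "id")

#' Exhaustive induced-subgraph census
#'
#' Enumerates every weakly connected induced subgraph of the requested sizes
#' exactly once with the ESU recursion (extension by exclusive neighbors with
#' id greater than the root, ascending id order), classifies each subgraph by
#' its canonical form, and stores the node subsets of the occurrences whose
#' class belongs to the dictionary.
#'
#' @param g a [DirectedGraph-class].
#' @param gamma graphlet dictionary, as returned by [enumerateGraphlets()];
#'   defaults to all graphlets of the requested sizes.
#' @param sizes integer vector of subgraph sizes to census (default: the
#'   distinct sizes present in `gamma`).
#' @param keepSubsets logical; when `FALSE` only counts are recorded, saving
#'   memory for count-based analyses such as the hypothesis-testing baseline.
#' @param maxOccurrences abort when the number of stored occurrences would
#'   exceed this budget (in-memory census only).
#' @return A [GraphletCensus-class].
#' @examples
#' g <- directedGraph(rbind(c(1, 2), c(2, 3), c(3, 1)))
#' census <- subgraphCensus(g, sizes = 3)
#' censusCounts(census)[censusCounts(census) > 0]
#' @export
subgraphCensus <- function(g, gamma = NULL, sizes = NULL, keepSubsets = TRUE,
                           maxOccurrences = 2e8) {
  stopifnot(is(g, "DirectedGraph"))
  if (is.null(gamma)) {
    if (is.null(sizes)) sizes <- 3:5
    gamma <- enumerateGraphlets(min(sizes), max(sizes))
    gamma <- Filter(function(x) x@n %in% sizes, gamma)
  }
  if (is.null(sizes)) sizes <- sort(unique(vapply(gamma, slot, integer(1), "n")))
  sizes <- as.integer(sizes)
  gn <- vapply(gamma, slot, integer(1), "n")
  gmask <- vapply(gamma, slot, integer(1), "mask")
  res <- .esu_census_cpp(g@N, g@edges - 1L, sizes, gn, gmask, keepSubsets)
  if (sum(res$counts) > maxOccurrences)
    stop("census exceeds the occurrence budget (", maxOccurrences,
         "); restrict sizes or use keepSubsets = FALSE")
  new("GraphletCensus", gamma = gamma, counts = as.numeric(res$counts),
      subsets = if (keepSubsets) res$subsets else list(),
      sizes = sizes, hasSubsets = keepSubsets)
}

#' Census counts per graphlet
#'
#' @param census a [GraphletCensus-class].
#' @return Named numeric vector of occurrence counts (names are graphlet ids).
#' @export
censusCounts <- function(census) {
  stats::setNames(census@counts, .gammaIds(census@gamma))
}

#' Occurrences of one graphlet as a matrix of node subsets
#'
#' @param census a [GraphletCensus-class] with stored subsets.
#' @param id graphlet id (or index into the dictionary).
#' @return Integer matrix, one row per occurrence, columns the (1-based,
#'   sorted) member node ids.
#' @export
occurrenceMatrix <- function(census, id) {
  if (!census@hasSubsets) stop("census was run with keepSubsets = FALSE")
  idx <- if (is.character(id)) match(id, .gammaIds(census@gamma)) else as.integer(id)
  if (is.na(idx) || idx < 1 || idx > length(census@gamma)) stop("unknown graphlet: ", id)
  k <- census@gamma[[idx]]@n
  v <- census@subsets[[idx]]
  matrix(v + 1L, ncol = k, byrow = TRUE)
}

setMethod("show", "GraphletCensus", function(object) {
  cat(sprintf("GraphletCensus: %d graphlets (sizes %s), %s occurrences%s\n",
              length(object@gamma), paste(object@sizes, collapse = ","),
              format(sum(object@counts), big.mark = ","),
              if (object@hasSubsets) "" else " (counts only)"))
})
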