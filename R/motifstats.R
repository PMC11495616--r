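# Topological summaries of inferred motif sets.

#' Count simple directed cycles of a small digraph
#'
#' Exhaustive enumeration of simple directed cycles of length >= 2 (each
#' cycle counted once, rooted at its smallest node). A reciprocal dyad is a
#' 2-cycle.
#'
#' @inheritParams canonicalForm
#' @return Integer cycle count.
#' @examples
#' countSimpleCycles(rbind(c(1, 2), c(2, 3), c(3, 1)), 3) # 1
#' @export
countSimpleCycles <- function(edges, n) {
  A <- matrix(FALSE, n, n)
  if (length(edges) > 0 && nrow(edges) > 0) A[as.matrix(edges)] <- TRUE
  count <- 0L
  walk <- function(start, current, visited) {
    for (nxt in seq_len(n)) {
      if (!A[current, nxt]) next
      if (nxt == start && length(visited) >= 2) count <<- count + 1L
      if (nxt > start && !(nxt %in% visited))
        walk(start, nxt, c(visited, nxt))
    }
  }
  for (s in seq_len(n)) walk(s, s, s)
  count
}

#' @noRd
.graphletMeasures <- function(gl) {
  e <- graphletEdges(gl)
  nE <- nrow(e)
  recip <- if (nE == 0) 0 else mean(paste(e[, 2], e[, 1]) %in% paste(e[, 1], e[, 2]))
  c(density = nE / (gl@n * (gl@n - 1)),
    reciprocity = recip,
    cycles = countSimpleCycles(e, gl@n))
}

#' Topological summary of a motif set
#'
#' Computes, per graphlet of the multiset, the edge density, the reciprocity
#' (fraction of edges whose reverse edge is present) and the number of
#' simple directed cycles, and returns multiset-weighted means together with
#' fixed-density random baselines: for each motif, the measures are averaged
#' over `nBaseline` random digraphs with the same node and edge counts.
#'
#' @param ms a [MotifSet-class] (nonempty).
#' @param nBaseline random graphlets per motif for the baseline (default
#'   100).
#' @param seed integer seed for the baseline draws.
#' @return A [MotifSummary-class].
#' @export
motifSummary <- function(ms, nBaseline = 100, seed = 1) {
  m <- multiplicities(ms)
  if (length(m) == 0) stop("motif set is empty")
  set.seed(seed)
  rows <- lapply(names(m), function(id) {
    gl <- graphletFromId(id)
    meas <- .graphletMeasures(gl)
    nE <- numEdges(gl)
    L <- gl@n * (gl@n - 1)
    base <- replicate(nBaseline, {
      bits <- sample.int(L, nE)
      e <- .edgesFromMask(gl@n, as.integer(sum(2^(bits - 1L))))
      rec <- if (nE == 0) 0 else mean(paste(e[, 2], e[, 1]) %in% paste(e[, 1], e[, 2]))
      c(density = nE / L, reciprocity = rec,
        cycles = countSimpleCycles(e, gl@n))
    })
    data.frame(id = id, n = gl@n, edges = nE, multiplicity = as.integer(m[[id]]),
               density = meas[["density"]], reciprocity = meas[["reciprocity"]],
               cycles = meas[["cycles"]],
               baselineDensity = mean(base["density", ]),
               baselineReciprocity = mean(base["reciprocity", ]),
               baselineCycles = mean(base["cycles", ]))
  })
  tab <- do.call(rbind, rows)
  w <- tab$multiplicity / sum(tab$multiplicity)
  means <- c(density = sum(w * tab$density),
             reciprocity = sum(w * tab$reciprocity),
             cycles = sum(w * tab$cycles))
  baselines <- c(density = sum(w * tab$baselineDensity),
                 reciprocity = sum(w * tab$baselineReciprocity),
                 cycles = sum(w * tab$baselineCycles))
  new("MotifSummary", perGraphlet = tab, means = means, baselines = baselines)
}

setMethod("show", "MotifSummary", function(object) {
  cat("MotifSummary (multiset-weighted means, baseline = fixed-density random):\n")
  for (nm in names(object@means))
    cat(sprintf("  %-12s %.3f (baseline %.3f)\n", nm, object@means[[nm]],
                object@baselines[[nm]]))
})

#' Motif prevalence and concentration across graphs
#'
#' For a collection of inferred motif sets (one per graph), computes per
#' graphlet the prevalence `p` -- the fraction of graphs whose motif set
#' contains it -- and the average concentration `c` -- the mean share it
#' takes of each nonempty motif set (graphs with empty motif sets are
#' excluded from the concentration average).
#'
#' @param motifSets list of [MotifSet-class] objects (or character vectors
#'   of graphlet ids).
#' @return data.frame with columns `id`, `prevalence`, `concentration`.
#' @export
motifPrevalence <- function(motifSets) {
  if (length(motifSets) == 0) stop("need at least one motif set")
  idLists <- lapply(motifSets, function(x) if (is(x, "MotifSet")) x@ids else as.character(x))
  ids <- sort(unique(unlist(idLists)))
  nG <- length(idLists)
  nonEmpty <- Filter(function(x) length(x) > 0, idLists)
  prev <- vapply(ids, function(id) {
    mean(vapply(idLists, function(s) id %in% s, logical(1)))
  }, numeric(1))
  conc <- vapply(ids, function(id) {
    if (length(nonEmpty) == 0) return(0)
    mean(vapply(nonEmpty, function(s) sum(s == id) / length(s), numeric(1)))
  }, numeric(1))
  data.frame(id = ids, prevalence = unname(prev), concentration = unname(conc))
}
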