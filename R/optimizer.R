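# Stochastic greedy motif-set search, multi-run protocol and model selection.

#' @noRd
.familyIndex <- function(base) match(base, .FAMILIES) - 1L

#' @noRd
.greedyRunRaw <- function(g, census, base, B, seed, gammaSize, logCandidates = 0L) {
  stopifnot(is(g, "DirectedGraph"), is(census, "GraphletCensus"))
  if (!census@hasSubsets) stop("greedy search needs a census with stored subsets")
  gamma <- census@gamma
  gn <- vapply(gamma, slot, integer(1), "n")
  gorient <- log2(vapply(gamma, slot, numeric(1), "orientations"))
  .greedy_run_cpp(g@N, g@edges - 1L, .familyIndex(base), gammaSize,
                  gn, gorient, census@subsets, as.integer(B),
                  as.integer(seed), as.integer(logCandidates))
}

#' @noRd
.replayState <- function(g, census, base, gammaSize, raw, upto) {
  state <- reductionState(g, base, gammaSize)
  if (upto < 1) return(state)
  for (t in seq_len(upto)) {
    gl <- census@gamma[[raw$contraction_graphlet[t] + 1L]]
    members <- raw$contraction_subsets[[t]] + 1L
    state <- contract(state, members, gl)
  }
  state
}

#' One stochastic greedy run
#'
#' Repeatedly samples a minibatch of up to `B` surviving census occurrences
#' per graphlet (discarding occurrences that overlap existing supernodes),
#' contracts the occurrence with the largest codelength gain, and continues
#' -- also through codelength increases -- until the census is exhausted.
#' The returned state is the codelength minimum along the trajectory.
#'
#' Ties in the batch argmax are broken deterministically: largest gain, then
#' smallest graphlet (dictionary order), then lexicographically smallest node
#' subset, so a fixed seed yields a bit-identical run.
#'
#' @param g a [DirectedGraph-class].
#' @param census a [GraphletCensus-class] of `g` with stored subsets.
#' @param base base model family for the reduced multigraph.
#' @param B minibatch size per graphlet (default 25).
#' @param seed integer seed of the run's private random stream.
#' @param gammaSize dictionary size for the motif-set code; defaults to the
#'   number of graphlets in the census dictionary.
#' @param logCandidates keep the first `logCandidates` per-candidate gains
#'   (iteration, graphlet, subset, gain) for diagnostics; attached as
#'   attribute `candidateLog`.
#' @return A [RunResult-class].
#' @export
greedyRun <- function(g, census, base = c("ER", "CM", "RER", "RCM"), B = 25,
                      seed = 1, gammaSize = NULL, logCandidates = 0) {
  base <- match.arg(base)
  if (is.null(gammaSize)) gammaSize <- length(census@gamma)
  raw <- .greedyRunRaw(g, census, base, B, seed, gammaSize, logCandidates)
  best <- raw$best_iteration
  state <- .replayState(g, census, base, gammaSize, raw, best)
  contractions <- lapply(seq_along(raw$contraction_gain), function(t) {
    list(graphlet = census@gamma[[raw$contraction_graphlet[t] + 1L]]@id,
         members = raw$contraction_subsets[[t]] + 1L,
         gain = raw$contraction_gain[t])
  })
  out <- new("RunResult", trajectory = raw$trajectory,
             bestIteration = as.integer(best), state = state,
             contractions = contractions, base = base, seed = as.integer(seed))
  if (logCandidates > 0) {
    attr(out, "candidateLog") <- list(
      iter = raw$candidate_iter, graphlet = raw$candidate_graphlet + 1L,
      gain = raw$candidate_gain,
      subsets = lapply(raw$candidate_subsets, function(s) s + 1L))
  }
  out
}

#' @rdname RunResult-class
#' @param x a [RunResult-class].
#' @export
setMethod("motifIds", "RunResult", function(x) x@state@motifs@ids)

setMethod("show", "RunResult", function(object) {
  cat(sprintf("RunResult (%s base, seed %d): L = %.2f bits at iteration %d of %d\n",
              object@base, object@seed, min(object@trajectory),
              object@bestIteration, length(object@trajectory) - 1L))
  show(object@state@motifs)
})

#' Sample one minibatch of census occurrences
#'
#' Reference implementation of the batch-sampling step: for each graphlet,
#' occurrences are drawn uniformly without replacement from the surviving
#' list until `B` non-overlapping ones are found or the list is exhausted.
#' Draws that overlap an existing supernode are discarded permanently;
#' batch members stay in the surviving pool (only the occurrence that ends
#' up contracted disappears, through the overlap rule, in later
#' iterations), so the search terminates exactly when no occurrence free of
#' supernodes remains. The compiled greedy engine performs the identical
#' procedure internally.
#'
#' @param occurrences list (one element per graphlet) of integer occurrence
#'   matrices, as from [occurrenceMatrix()].
#' @param state a [ReductionState-class] (defines which nodes are absorbed).
#' @param B minibatch size per graphlet.
#' @return A list with `batch` (list of `list(graphlet = index, members)`)
#'   and `occurrences` (the pruned surviving lists).
#' @export
sampleBatch <- function(occurrences, state, B) {
  batch <- list()
  for (gi in seq_along(occurrences)) {
    occ <- occurrences[[gi]]
    if (is.null(occ) || nrow(occ) == 0) next
    taken <- 0L
    keepRows <- rep(TRUE, nrow(occ))
    avail <- seq_len(nrow(occ))
    while (taken < B && length(avail) > 0) {
      pick <- avail[sample.int(length(avail), 1)]
      avail <- setdiff(avail, pick)
      members <- occ[pick, ]
      if (nonOverlapping(state, members)) {
        batch[[length(batch) + 1L]] <- list(graphlet = gi, members = members)
        taken <- taken + 1L
      } else {
        keepRows[pick] <- FALSE
      }
    }
    occurrences[[gi]] <- occ[keepRows, , drop = FALSE]
  }
  list(batch = batch, occurrences = occurrences)
}

#' No-hypercompression p-value bound
#'
#' The probability that a wrong model out-compresses the data-generating one
#' by `K` bits is at most `2^-K`; clipped to 1 for nonpositive `K`.
#'
#' @param K codelength difference in bits.
#' @return Upper bound on the p-value.
#' @examples
#' pvalueBound(10)
#' @export
pvalueBound <- function(K) pmin(1, 2^(-K))

#' Cross-model motif-set selection
#'
#' Runs the greedy search `nRuns` times for each multigraph base family,
#' computes the four motif-free simple-graph reference codelengths, and
#' selects the overall shortest description. The compressibility
#' `deltaLstar` is measured against the simple Erdos-Renyi code (always a
#' candidate, so it is nonnegative); `deltaLmotifs` -- reported only when a
#' motif-based model wins -- is the number of bits the motif encoding gains
#' over the best motif-free model.
#'
#' @param g a [DirectedGraph-class].
#' @param census optional precomputed [GraphletCensus-class] with subsets;
#'   computed from `sizes` when missing and shared across all runs.
#' @param sizes censused subgraph sizes when `census` is not supplied.
#' @param bases base families to search (default all four).
#' @param nRuns greedy runs per family.
#' @param B minibatch size per graphlet.
#' @param seed master seed; each run uses an independently derived stream.
#' @param gammaSize dictionary size for the motif-set code.
#' @return A [SelectionReport-class].
#' @export
selectModel <- function(g, census = NULL, sizes = 3:5,
                        bases = c("ER", "CM", "RER", "RCM"), nRuns = 5,
                        B = 25, seed = 1, gammaSize = NULL) {
  stopifnot(is(g, "DirectedGraph"))
  if (is.null(census)) census <- subgraphCensus(g, sizes = sizes)
  if (is.null(gammaSize)) gammaSize <- length(census@gamma)
  bases <- match.arg(bases, .FAMILIES, several.ok = TRUE)

  refs <- vapply(bases, function(f) motifFreeCodeLength(g, f), numeric(1))
  runL <- list()
  bestRaw <- NULL; bestRawL <- Inf; bestBase <- NA_character_; bestSeed <- NA_integer_
  for (fi in seq_along(bases)) {
    f <- bases[fi]
    Ls <- numeric(nRuns)
    for (r in seq_len(nRuns)) {
      runSeed <- as.integer((seed + 7919 * ((fi - 1L) * nRuns + r)) %% 2147483629)
      raw <- .greedyRunRaw(g, census, f, B, runSeed, gammaSize)
      Ls[r] <- min(raw$trajectory)
      if (Ls[r] < bestRawL) {
        bestRawL <- Ls[r]; bestRaw <- raw; bestBase <- f; bestSeed <- runSeed
      }
    }
    runL[[f]] <- Ls
  }
  bestMotif <- vapply(runL, min, numeric(1))
  models <- data.frame(family = bases, motifFree = unname(refs),
                       bestMotif = unname(bestMotif[bases]))

  bestFreeL <- min(refs)
  motifWins <- bestRawL < bestFreeL
  if (motifWins) {
    state <- .replayState(g, census, bestBase, gammaSize, bestRaw,
                          bestRaw$best_iteration)
    motifs <- state@motifs
    if (length(motifs) == 0) motifWins <- FALSE
  }
  if (motifWins) {
    contractions <- lapply(seq_along(bestRaw$contraction_gain), function(t) {
      list(graphlet = census@gamma[[bestRaw$contraction_graphlet[t] + 1L]]@id,
           members = bestRaw$contraction_subsets[[t]] + 1L,
           gain = bestRaw$contraction_gain[t])
    })
    run <- new("RunResult", trajectory = bestRaw$trajectory,
               bestIteration = as.integer(bestRaw$best_iteration),
               state = state, contractions = contractions,
               base = bestBase, seed = bestSeed)
    bestLabel <- paste0(bestBase, "+motifs")
    codelength <- bestRawL
    deltaLmotifs <- bestFreeL - bestRawL
    bestList <- list(run)
  } else {
    bestLabel <- bases[which.min(refs)]
    codelength <- bestFreeL
    deltaLmotifs <- NA_real_
    motifs <- motifSet()
    bestList <- list()
  }
  deltaLstar <- motifFreeCodeLength(g, "ER") - codelength
  new("SelectionReport", models = models, best = bestList,
      bestLabel = bestLabel, codelength = codelength,
      deltaLstar = deltaLstar, deltaLmotifs = deltaLmotifs,
      pBound = pvalueBound(deltaLstar), runCodelengths = runL,
      motifs = motifs)
}

#' @rdname SelectionReport-class
#' @param x a [SelectionReport-class].
#' @export
setMethod("motifIds", "SelectionReport", function(x) x@motifs@ids)

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: best model %s, L = %.2f bits\n",
              object@bestLabel, object@codelength))
  cat(sprintf("  compressibility vs simple ER: %.2f bits (p <= %.3g)\n",
              object@deltaLstar, object@pBound))
  if (!is.na(object@deltaLmotifs))
    cat(sprintf("  motif gain over best dyadic model: %.2f bits\n",
                object@deltaLmotifs))
  print(object@models, row.names = FALSE)
})
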