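# Classic hypothesis-testing motif mining (the frequentist comparator).

#' Hypothesis-testing motif mining
#'
#' The traditional pipeline: census the graphlet counts of the observed
#' graph, estimate each graphlet's null distribution from `nNull` randomized
#' replicates under a chosen null family, and flag as motifs the graphlets
#' whose observed count is significantly over-represented (one-sided) after
#' a Bonferroni correction that multiplies raw p-values by the dictionary
#' size.
#'
#' By default raw p-values come from a Gaussian approximation of the null
#' (`z = (N_obs - mean)/sd`, with `z = 0` when the null is degenerate);
#' `empirical = TRUE` switches to empirical upper-tail p-values
#' `(1 + #null >= obs)/(nNull + 1)`, which cannot reach Bonferroni-scale
#' significance unless `nNull` is very large.
#'
#' @param g a [DirectedGraph-class].
#' @param sizes graphlet sizes to census (default 3:4; the 5-node census of
#'   many null replicates is the expensive step).
#' @param nullFamily null-model family used for randomization.
#' @param nNull number of null replicates (>= 2).
#' @param alpha uncorrected significance threshold (default 0.01).
#' @param seed integer seed.
#' @param empirical use empirical instead of Gaussian p-values.
#' @param gamma optional restricted dictionary.
#' @return An [HTResult-class].
#' @export
htMotifMining <- function(g, sizes = 3:4, nullFamily = c("ER", "CM", "RER", "RCM"),
                          nNull = 50, alpha = 0.01, seed = 1, empirical = FALSE,
                          gamma = NULL) {
  nullFamily <- match.arg(nullFamily)
  stopifnot(nNull >= 2)
  if (is.null(gamma)) {
    gamma <- enumerateGraphlets(min(sizes), max(sizes))
    gamma <- Filter(function(x) x@n %in% sizes, gamma)
  }
  obs <- subgraphCensus(g, gamma = gamma, sizes = sizes, keepSubsets = FALSE)@counts
  nullCounts <- matrix(0, nNull, length(gamma))
  for (r in seq_len(nNull)) {
    gr <- randomizeGraph(g, nullFamily, seed = as.integer((seed + 613 * r) %% 2147483629))
    nullCounts[r, ] <- subgraphCensus(gr, gamma = gamma, sizes = sizes,
                                      keepSubsets = FALSE)@counts
  }
  mu <- colMeans(nullCounts)
  sdv <- apply(nullCounts, 2, sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  if (empirical) {
    praw <- vapply(seq_along(obs), function(i) {
      (1 + sum(nullCounts[, i] >= obs[i])) / (nNull + 1)
    }, numeric(1))
  } else {
    praw <- pnorm(z, lower.tail = FALSE)
  }
  gammaSize <- length(gamma)
  pcorr <- pmin(1, praw * gammaSize)
  flagged <- obs > 0 & z > 0 & praw * gammaSize < alpha
  tab <- data.frame(id = vapply(gamma, slot, character(1), "id"),
                    n = vapply(gamma, slot, integer(1), "n"),
                    observed = obs, nullMean = mu, nullSd = sdv, z = z,
                    pRaw = praw, pCorrected = pcorr, motif = flagged)
  new("HTResult", table = tab,
      settings = list(nullFamily = nullFamily, nNull = nNull, alpha = alpha,
                      gammaSize = gammaSize, sizes = sizes,
                      empirical = empirical, seed = seed))
}

setMethod("show", "HTResult", function(object) {
  nf <- sum(object@table$motif)
  cat(sprintf("HTResult (%s null, %d replicates): %d of %d graphlets flagged at alpha = %g\n",
              object@settings$nullFamily, object@settings$nNull, nf,
              nrow(object@table), object@settings$alpha))
  if (nf > 0) print(head(object@table[object@table$motif, ], 10), row.names = FALSE)
})
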