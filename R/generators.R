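# Synthetic inputs: the planted-motif generator (the generative inverse of
# subgraph contraction) and microcanonical null-model randomizers.

#' Generate a graph with planted motifs
#'
#' Inverts the compression scheme: (i) marks random latent nodes as
#' supernodes carrying the prescribed graphlets; (ii) draws a latent
#' Erdos-Renyi multigraph by throwing `ELatent` multiedges uniformly over
#' ordered node pairs, conditioned on the support of the contraction code
#' (a throw that would exceed a pair's wiring capacity -- more than one edge
#' between two plain nodes, more than `n_s` towards a supernode, more than
#' `n_s n_s'` between two supernodes -- is redrawn, so the generated graph is
#' always realizable as a simple graph with exactly predictable node and
#' edge counts); (iii) expands every supernode into its graphlet under a
#' uniformly random orientation and wires each incident latent multiedge
#' uniformly over its binomial wiring configurations (distinct internal
#' endpoints; distinct internal pairs between two supernodes).
#'
#' @param NLatent,ELatent latent multigraph size.
#' @param placements motifs to plant: a named integer vector mapping graphlet
#'   ids to copy numbers, e.g. `c("d5-fffff" = 20)`.
#' @param seed integer seed.
#' @param maxRetries budget of consecutive rejected throws before giving up
#'   (only reachable when the total wiring capacity is nearly exhausted).
#' @return A list with `graph` (the [DirectedGraph-class]), `groundTruth`
#'   (per planted copy: graphlet id and member node ids), and `latent`
#'   (the latent features `N` and `E`).
#' @examples
#' pm <- plantMotifs(30, 80, c("d5-fffff" = 2), seed = 1) # two 5-cliques
#' numNodes(pm$graph) # 30 + 2 * 4
#' @export
plantMotifs <- function(NLatent, ELatent, placements, seed = 1,
                        maxRetries = 200) {
  set.seed(seed)
  glets <- lapply(names(placements), graphletFromId)
  copies <- as.integer(placements)
  supGlets <- rep(glets, copies)
  nSup <- length(supGlets)
  if (nSup > NLatent) stop("more supernodes than latent nodes")

  supNodes <- sample.int(NLatent, nSup)
  size <- rep(1L, NLatent)
  size[supNodes] <- vapply(supGlets, slot, integer(1), "n")
  cap <- outer(size, size)       # wiring capacity per ordered pair
  diag(cap) <- 0L
  if (sum(cap) < ELatent) stop("latent edge count exceeds total wiring capacity")

  # latent ER multigraph conditioned on the code's support
  A <- matrix(0L, NLatent, NLatent)
  thrown <- 0L
  failed <- 0L
  while (thrown < ELatent) {
    i <- sample.int(NLatent, 1); j <- sample.int(NLatent, 1)
    if (i == j || A[i, j] >= cap[i, j]) {
      failed <- failed + 1L
      if (failed > maxRetries * ELatent)
        stop("could not place the latent multiedges; capacity nearly exhausted")
      next
    }
    A[i, j] <- A[i, j] + 1L
    thrown <- thrown + 1L
  }

  {
    # allocate final node ids
    members <- vector("list", NLatent)
    nextId <- 0L
    for (v in seq_len(NLatent)) {
      members[[v]] <- nextId + seq_len(size[v])
      nextId <- nextId + size[v]
    }
    NG <- nextId
    edges <- NULL
    groundTruth <- list()
    # internal edges under a random orientation
    for (si in seq_len(nSup)) {
      v <- supNodes[si]
      gl <- supGlets[[si]]
      perm <- sample.int(gl@n)
      ge <- graphletEdges(gl)
      edges <- rbind(edges, cbind(members[[v]][perm[ge[, 1]]],
                                  members[[v]][perm[ge[, 2]]]))
      groundTruth[[si]] <- list(graphlet = gl@id, members = members[[v]],
                                orientation = perm)
    }
    # external wiring of the latent multiedges
    for (u in seq_len(NLatent)) for (v in seq_len(NLatent)) {
      m <- A[u, v]
      if (m == 0L) next
      mu <- members[[u]]; mv <- members[[v]]
      if (length(mu) == 1L && length(mv) == 1L) {
        edges <- rbind(edges, cbind(mu, mv))
      } else if (length(mv) == 1L) {
        src <- mu[sample.int(length(mu), m)]
        edges <- rbind(edges, cbind(src, rep(mv, m)))
      } else if (length(mu) == 1L) {
        dst <- mv[sample.int(length(mv), m)]
        edges <- rbind(edges, cbind(rep(mu, m), dst))
      } else {
        pick <- sample.int(length(mu) * length(mv), m) - 1L
        src <- mu[pick %% length(mu) + 1L]
        dst <- mv[pick %/% length(mu) + 1L]
        edges <- rbind(edges, cbind(src, dst))
      }
    }
    g <- directedGraph(edges, N = NG)
    list(graph = g, groundTruth = groundTruth,
         latent = list(N = NLatent, E = ELatent, A = A))
  }
}

#' Latent parameters for a planted-motif benchmark
#'
#' Helper translating a target final graph size and density into latent
#' parameters: planting `m` copies of an `n`-node graphlet adds `m (n - 1)`
#' nodes and `m e` edges during expansion.
#'
#' @param N,rho target node count and edge density of the generated graph.
#' @param placements named integer vector of graphlet ids and copy numbers.
#' @return A list with `NLatent` and `ELatent`.
#' @export
plantedLatentParams <- function(N, rho, placements) {
  glets <- lapply(names(placements), graphletFromId)
  copies <- as.integer(placements)
  extraNodes <- sum(copies * (vapply(glets, slot, integer(1), "n") - 1L))
  extraEdges <- sum(copies * vapply(glets, numEdges, integer(1)))
  E <- round(rho * N * (N - 1))
  list(NLatent = as.integer(N - extraNodes), ELatent = as.integer(E - extraEdges))
}

#' Randomize a graph under a microcanonical null model
#'
#' Draws a random simple digraph that exactly preserves the constrained
#' features of the chosen family: uniform resampling for ER (node and edge
#' counts) and RER (additionally the reciprocated/non-reciprocated edge
#' split), and Markov-chain double-edge swaps for CM (all in- and
#' out-degrees) and RCM (reciprocal and non-reciprocated degrees, with swaps
#' applied separately within the reciprocated and non-reciprocated
#' subgraphs and moves that would merge the two rejected).
#'
#' @param g a [DirectedGraph-class].
#' @param family null-model family.
#' @param seed integer seed.
#' @param swapFactor accepted swaps per edge for the swap-based families
#'   (default 10).
#' @return A [DirectedGraph-class] with the same node set and labels.
#' @export
randomizeGraph <- function(g, family = c("ER", "CM", "RER", "RCM"), seed = 1,
                           swapFactor = 10) {
  family <- match.arg(family)
  stopifnot(is(g, "DirectedGraph"))
  N <- g@N
  E <- nrow(g@edges)
  seed <- as.integer(seed)
  if (family == "ER") {
    edges <- .er_resample_cpp(N, E, seed) + 1L
  } else if (family == "RER") {
    H <- asMultigraph(g)
    edges <- .rer_resample_cpp(N, reciprocatedEdgeCount(H),
                               nonReciprocatedEdgeCount(H), seed) + 1L
  } else {
    fun <- if (family == "CM") .cm_swap_cpp else .rcm_swap_cpp
    # lazy chain: 4x steps gives ~2x swapFactor*E proposals, half lazy
    res <- fun(N, g@edges - 1L, 4 * swapFactor * E, seed)
    if (res$accepted == 0 && E >= 2)
      warning("no valid swap was accepted; the graph may admit no swaps")
    edges <- res$edges + 1L
  }
  directedGraph(edges, N = N, labels = g@labels)
}

#' Synthetic connectome-like reference graph
#'
#' A stand-in for an empirical microcircuit wiring diagram used to
#' parameterize null-model benchmarks: heavy-tailed (log-normal) connection
#' propensities produce skewed in- and out-degree sequences, and a
#' prescribed fraction of edges is laid down as reciprocated pairs --
#' the two features that distinguish real connectomes from uniform random
#' graphs. This graph is synthetic; it matches published connectome summary
#' statistics (size, density, reciprocity) but no real wiring.
#'
#' @param N,E node and edge counts (defaults match a mushroom-body-sized
#'   microcircuit).
#' @param reciprocatedFraction fraction of edges that belong to reciprocated
#'   pairs.
#' @param sdlog log-normal spread of node propensities.
#' @param seed integer seed.
#' @return A [DirectedGraph-class].
#' @export
connectomeLikeGraph <- function(N = 198, E = 6499, reciprocatedFraction = 0.3,
                                sdlog = 0.8, seed = 1) {
  set.seed(seed)
  Em <- round(reciprocatedFraction * E / 2)
  Ed <- E - 2 * Em
  w <- stats::rlnorm(N, 0, sdlog)
  A <- matrix(0L, N, N)
  used <- matrix(FALSE, N, N)
  placePair <- function() {
    repeat {
      i <- sample.int(N, 1, prob = w); j <- sample.int(N, 1, prob = w)
      if (i != j && !used[i, j] && !used[j, i]) return(c(i, j))
    }
  }
  for (q in seq_len(Em)) {
    p <- placePair()
    A[p[1], p[2]] <- 1L; A[p[2], p[1]] <- 1L
    used[p[1], p[2]] <- TRUE; used[p[2], p[1]] <- TRUE
  }
  for (q in seq_len(Ed)) {
    p <- placePair()
    A[p[1], p[2]] <- 1L
    used[p[1], p[2]] <- TRUE; used[p[2], p[1]] <- TRUE
  }
  directedGraph(which(A == 1L, arr.ind = TRUE), N = N)
}
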