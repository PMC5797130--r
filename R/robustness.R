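#' Multiplex connectivity
#'
#' A multiplex network is connected when every pair of words is mutually
#' reachable allowing traversal along links of any layer, i.e. when the
#' aggregate (layer-union) graph is connected.
#'
#' @param M a `multiplex` object.
#' @return logical.
#' @export
is_connected <- function(M) {
  igraph::is_connected(aggregate_graph(M))
}

#' Multiplex closeness centrality
#'
#' Closeness of word i is `(N - 1) / sum_j d(i, j)` with hop distances taken
#' on the aggregate graph: since switching layer at a word carries no cost in
#' a node-aligned multiplex, shortest paths across the whole multiplex reduce
#' to shortest paths on the union of the layers. The median closeness over
#' words serves as the headline navigability measure.
#'
#' @param M a `multiplex` object with a connected aggregate graph.
#' @param harmonic_fallback on a disconnected aggregate, return normalised
#'   harmonic closeness instead of erroring.
#' @return list with `closeness` (named numeric per word), `median`, `mean`.
#' @export
multiplex_closeness <- function(M, harmonic_fallback = FALSE) {
  g <- aggregate_graph(M)
  if (!igraph::is_connected(g)) {
    if (!harmonic_fallback)
      stop("aggregate graph is disconnected; closeness undefined ",
           "(set harmonic_fallback = TRUE for harmonic closeness)")
    cl <- igraph::harmonic_centrality(g, normalized = TRUE)
  } else {
    cl <- igraph::closeness(g, normalized = TRUE)
  }
  names(cl) <- M$nodes
  list(closeness = cl, median = stats::median(cl), mean = mean(cl))
}

#' Targeted word removal experiment
#'
#' Simulates progressive anomia: words from a target pool fail (are removed
#' from every layer at once) in uniformly random order, and the median
#' multiplex closeness of the surviving lexicon is recorded every `step`
#' removals. With a `degree_match_pool`, the removal sequence is replaced by
#' a multidegree-matched counterpart drawn from that pool (the
#' degree-corrected out-group control: same degrees, different words). The
#' aggregate graph is checked after each batch; if a removal disconnects it
#' the repetition stops early with a warning.
#'
#' @param M a `multiplex` object.
#' @param pool character vector of removable words.
#' @param max_removed maximum words removed, at most `length(pool)`.
#' @param step removals between successive closeness measurements.
#' @param repetitions independent removal sequences.
#' @param seed master seed.
#' @param degree_match_pool optional pool from which a multidegree-matched
#'   counterpart of each sampled removal sequence is drawn.
#' @return a `removal_experiment`: data frame with columns `removed`,
#'   `median_closeness` (mean over repetitions), `sd`, `mean_closeness`,
#'   plus attributes `repetitions` and `strategy`.
#' @export
removal_experiment <- function(M, pool, max_removed = length(pool),
                               step = 25, repetitions = 50, seed = NULL,
                               degree_match_pool = NULL) {
  pool <- as.character(pool)
  if (!length(pool)) stop("empty removal pool")
  if (max_removed > length(pool))
    stop("max_removed exceeds the pool size")
  if (anyNA(match(pool, M$nodes))) stop("unknown words in pool")
  checkpoints <- unique(c(seq(0, max_removed, by = step), max_removed))
  seeds <- derive_seeds(seed, repetitions)
  med <- matrix(NA_real_, nrow = length(checkpoints), ncol = repetitions)
  avg <- matrix(NA_real_, nrow = length(checkpoints), ncol = repetitions)
  for (r in seq_len(repetitions)) {
    seq_r <- with_seed(seeds[r], sample(pool, max_removed))
    if (!is.null(degree_match_pool)) {
      dm <- degree_corrected_sample(M, seq_r,
                                    setdiff(degree_match_pool, seq_r),
                                    seed = seeds[r])
      seq_r <- dm$matched
    }
    for (ci in seq_along(checkpoints)) {
      k <- checkpoints[ci]
      keep <- setdiff(M$nodes, seq_r[seq_len(k)])
      sub <- induced_subnetwork(M, keep)
      if (!is_connected(sub)) {
        warning(sprintf(
          "repetition %d: aggregate disconnected after %d removals; stopping",
          r, k))
        break
      }
      cl <- multiplex_closeness(sub)
      med[ci, r] <- cl$median
      avg[ci, r] <- cl$mean
    }
  }
  out <- data.frame(removed = checkpoints,
                    median_closeness = rowMeans(med, na.rm = TRUE),
                    sd = apply(med, 1, stats::sd, na.rm = TRUE),
                    mean_closeness = rowMeans(avg, na.rm = TRUE))
  attr(out, "repetitions") <- repetitions
  class(out) <- c("removal_experiment", "data.frame")
  out
}
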