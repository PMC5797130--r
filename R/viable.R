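#' Viable clusters of a multiplex network
#'
#' A viable cluster is a set of words whose induced subgraph is connected on
#' every layer considered in isolation: any member can be reached from any
#' other member without leaving the set, using links of one single layer at a
#' time, for each layer. These are the mutually connected components of
#' multiplex percolation theory. A cluster is called "trivial" when it has at
#' most two members (two words joined by the same link on every layer form
#' the smallest possible viable cluster).
#'
#' `maximal_viable_clusters()` computes all maximal viable clusters by
#' partition refinement: starting from the whole node set, every candidate
#' block is repeatedly split into the connected components of each layer's
#' induced subgraph until the partition stabilises. The fixpoint blocks are
#' exactly the maximal viable clusters, which are pairwise disjoint and
#' unique.
#'
#' @param M a `multiplex` object.
#' @param include_trivial also return clusters of size 2 (size-1 fixpoints are
#'   never reported).
#' @return list of `viable_cluster` objects, sorted by decreasing size (ties
#'   broken by lexicographically smallest member set). Each has elements
#'   `members` (character) and `per_layer_connected` (named logical, all
#'   `TRUE` by construction).
#' @seealso [largest_viable_cluster()], [brute_force_viable_clusters()]
#' @export
maximal_viable_clusters <- function(M, include_trivial = FALSE) {
  n <- length(M$nodes)
  adj <- multiplex_adjacency(M)
  blocks <- refine_viable_partition(adj, n)
  min_size <- if (include_trivial) 2L else 3L
  blocks <- Filter(function(b) length(b) >= min_size, blocks)
  clusters <- lapply(blocks, function(b) new_viable_cluster(M, M$nodes[b]))
  order_clusters(clusters)
}

new_viable_cluster <- function(M, members) {
  members <- sort(as.character(members), method = "radix")
  structure(list(members = members,
                 per_layer_connected =
                   stats::setNames(rep(TRUE, length(M$layers)), M$layers)),
            class = "viable_cluster")
}

#' @export
print.viable_cluster <- function(x, ...) {
  cat(sprintf("viable cluster: %d words\n", length(x$members)))
  invisible(x)
}

order_clusters <- function(clusters) {
  if (!length(clusters)) return(clusters)
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  first <- vapply(clusters, function(cl) cl$members[1], "")
  clusters[order(-sizes, first, method = "radix")]
}

## partition refinement on integer node indices; returns list of integer
## vectors (blocks of size >= 2 that are connected on every layer)
refine_viable_partition <- function(adj, n) {
  n_layers <- length(adj)
  queue <- list(seq_len(n))
  done <- list()
  while (length(queue)) {
    b <- queue[[1]]; queue <- queue[-1]
    if (length(b) < 2L) next
    mask <- logical(n); mask[b] <- TRUE
    split_found <- FALSE
    for (l in seq_len(n_layers)) {
      comp <- bfs_component(b[1], adj[[l]], mask)
      if (sum(comp) < length(b)) {
        ## split block into this layer's components and re-queue
        pieces <- list()
        remaining <- mask
        seeds <- b
        while (any(remaining)) {
          s <- seeds[remaining[seeds]][1]
          piece <- bfs_component(s, adj[[l]], remaining)
          pieces[[length(pieces) + 1L]] <- which(piece)
          remaining <- remaining & !piece
        }
        queue <- c(queue, pieces)
        split_found <- TRUE
        break
      }
    }
    if (!split_found) done[[length(done) + 1L]] <- b
  }
  done
}

#' Largest viable cluster (LVC)
#'
#' The largest non-trivial (more than two members) viable cluster of the
#' multiplex, or an empty cluster when none exists. For a single-layer
#' network this coincides exactly with the largest connected component.
#'
#' @param M a `multiplex` object.
#' @param include_trivial allow size-2 clusters to qualify.
#' @return a `viable_cluster`; `members` is `character(0)` when no qualifying
#'   cluster exists.
#' @export
largest_viable_cluster <- function(M, include_trivial = FALSE) {
  cl <- maximal_viable_clusters(M, include_trivial = include_trivial)
  if (!length(cl)) return(new_viable_cluster(M, character(0)))
  cl[[1]]
}

#' Brute-force viable cluster oracle
#'
#' Enumerates every node subset of size at least two, keeps those whose
#' induced subgraph is connected on every layer, and returns the maximal ones
#' under set inclusion. Exponential in the number of nodes, therefore guarded
#' at 15 nodes; intended purely as an independent correctness oracle for
#' [maximal_viable_clusters()] on small instances.
#'
#' @param M a `multiplex` object with at most 15 nodes.
#' @param include_trivial also return maximal clusters of size 2.
#' @return list of `viable_cluster` objects, sorted as in
#'   [maximal_viable_clusters()].
#' @export
brute_force_viable_clusters <- function(M, include_trivial = FALSE) {
  n <- length(M$nodes)
  if (n > 15L) stop("brute-force oracle limited to 15 nodes")
  ## bitmask adjacency per layer: bit k-1 set in adjbits[[l]][v] iff v~k
  adjbits <- lapply(M$edges, function(e) {
    ab <- integer(n)
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1]; j <- e[r, 2]
      ab[i] <- bitwOr(ab[i], bitwShiftL(1L, j - 1L))
      ab[j] <- bitwOr(ab[j], bitwShiftL(1L, i - 1L))
    }
    ab
  })
  connected_mask <- function(sub) {
    members <- which(bitwAnd(sub, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    for (ab in adjbits) {
      ## cheap necessary condition: no member may be isolated within the set
      if (any(bitwAnd(ab[members], sub) == 0L)) return(FALSE)
      reach <- bitwShiftL(1L, members[1] - 1L)
      repeat {
        grow <- reach
        for (v in members) {
          vb <- bitwShiftL(1L, v - 1L)
          if (bitwAnd(reach, vb) != 0L)
            grow <- bitwOr(grow, bitwAnd(ab[v], sub))
        }
        if (grow == reach) break
        reach <- grow
      }
      if (reach != sub) return(FALSE)
    }
    TRUE
  }
  subsets <- seq_len(bitwShiftL(1L, n) - 1L)
  sizes <- vapply(subsets, function(s) popcount(s), 0L)
  min_size <- if (include_trivial) 2L else 3L
  cand <- subsets[sizes >= min_size]
  cand <- cand[order(-sizes[sizes >= min_size])]
  maximal <- integer(0)
  for (s in cand) {
    contained <- FALSE
    for (m in maximal)
      if (bitwAnd(s, m) == s) { contained <- TRUE; break }
    if (!contained && connected_mask(s)) maximal <- c(maximal, s)
  }
  clusters <- lapply(maximal, function(m) {
    members <- M$nodes[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    new_viable_cluster(M, members)
  })
  order_clusters(clusters)
}

popcount <- function(x) {
  cnt <- 0L
  while (x > 0L) { cnt <- cnt + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  cnt
}
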