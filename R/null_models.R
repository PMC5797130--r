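#' Degree-preserving configuration rewiring
#'
#' Randomises each layer independently with double-edge swaps, which preserve
#' every word's within-layer degree exactly (hence the per-layer degree
#' sequence and edge count). Swaps that would introduce a self-loop or a
#' multi-edge are rejected. Rewiring proceeds until the requested fraction of
#' the layer's original links has been displaced; with `fraction = 1` an
#' additional burn-in of ten times the layer's edge count in attempted swaps
#' is performed so that the layer approaches a uniform draw from the
#' configuration model. Attempts are capped at one hundred times the number
#' of requested swaps; hitting the cap raises a warning.
#'
#' @param M a `multiplex` object.
#' @param fraction proportion of intra-layer links to displace, in `[0, 1]`.
#' @param seed integer seed.
#' @return a rewired `multiplex` with identical node set, layers and
#'   per-layer degree sequences.
#' @export
configuration_rewire <- function(M, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("'fraction' must lie in [0, 1]")
  if (fraction == 0) return(M)
  with_seed(seed, {
    edges <- lapply(M$layers, function(ln)
      rewire_layer(M$edges[[ln]], length(M$nodes), fraction, ln))
    names(edges) <- M$layers
    structure(list(nodes = M$nodes, layers = M$layers, edges = edges),
              class = "multiplex")
  })
}

rewire_layer <- function(e, n, fraction, layer_name) {
  m <- nrow(e)
  if (m < 2L) {
    warning(sprintf("layer '%s' has fewer than 2 edges; left unchanged",
                    layer_name))
    return(e)
  }
  ## adjacency sets for O(deg) membership tests
  ends <- c(e[, 1], e[, 2]); nbrs <- c(e[, 2], e[, 1])
  o <- order(ends)
  adj <- unname(split(nbrs[o], factor(ends[o], levels = seq_len(n))))
  cur <- e                       # current edge list (rows mutate in place)
  ## hash of the original edge set, to track how many originals are displaced
  orig <- new.env(hash = TRUE, size = 2L * m)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  for (r in seq_len(m)) assign(ekey(e[r, 1], e[r, 2]), TRUE, envir = orig)
  is_orig <- function(a, b) !is.null(orig[[ekey(a, b)]])
  ## fraction = 1 means full randomisation: run the burn-in and accept the
  ## residual overlap a configuration model naturally retains
  target_moved <- if (fraction >= 1) 0L else max(1L, round(fraction * m))
  burn_in <- if (fraction >= 1) 10L * m else 0L
  max_attempts <- 100L * max(target_moved, burn_in)
  attempts <- 0L
  moved <- 0L                    # count of original edges currently absent
  has_edge <- function(a, b) b %in% adj[[a]]
  drop_nbr <- function(a, b) adj[[a]] <<- adj[[a]][-match(b, adj[[a]])]
  while ((moved < target_moved || attempts < burn_in) &&
         attempts < max_attempts) {
    attempts <- attempts + 1L
    rows <- sample.int(m, 2L)
    a <- cur[rows[1], 1]; b <- cur[rows[1], 2]
    c <- cur[rows[2], 1]; d <- cur[rows[2], 2]
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    ## propose a-d, c-b
    if (a == d || c == b || a == c || b == d) next
    if (has_edge(a, d) || has_edge(c, b)) next
    drop_nbr(a, b); drop_nbr(b, a); drop_nbr(c, d); drop_nbr(d, c)
    adj[[a]] <- c(adj[[a]], d); adj[[d]] <- c(adj[[d]], a)
    adj[[c]] <- c(adj[[c]], b); adj[[b]] <- c(adj[[b]], c)
    moved <- moved + is_orig(a, b) + is_orig(c, d) -
      is_orig(a, d) - is_orig(c, b)
    cur[rows[1], ] <- c(min(a, d), max(a, d))
    cur[rows[2], ] <- c(min(c, b), max(c, b))
  }
  if (attempts >= max_attempts && moved < target_moved)
    warning(sprintf("layer '%s': swap attempt cap reached (%d/%d links moved)",
                    layer_name, moved, target_moved))
  canonical_edges(cur[, 1], cur[, 2])
}

#' Full label reshuffling null model
#'
#' Applies an independent uniform permutation of word labels to every layer's
#' edge list (optionally restricted to a node subset). Each layer remains
#' isomorphic to its original, so all within-layer structure is preserved,
#' but the identification of words across layers is destroyed: a word's
#' neighbourhood on one layer no longer corresponds to the same word's
#' neighbourhood on another. On correlated multiplexes this removes the
#' inter-layer alignment that viable clusters depend on.
#'
#' @param M a `multiplex` object.
#' @param seed integer seed.
#' @param subset character vector of words within which labels are permuted
#'   (default: all nodes).
#' @return a relabelled `multiplex` on the same node set.
#' @export
full_reshuffle <- function(M, seed = NULL, subset = NULL) {
  n <- length(M$nodes)
  idx <- if (is.null(subset)) seq_len(n) else {
    i <- match(as.character(subset), M$nodes)
    if (anyNA(i)) stop("subset contains unknown words")
    i
  }
  with_seed(seed, {
    edges <- lapply(M$edges, function(e) {
      perm <- seq_len(n)
      perm[idx] <- idx[sample.int(length(idx))]
      canonical_edges(perm[e[, 1]], perm[e[, 2]])
    })
    structure(list(nodes = M$nodes, layers = M$layers, edges = edges),
              class = "multiplex")
  })
}

#' Targeted full reshuffling of selected words
#'
#' [full_reshuffle()] restricted to a chosen word set, e.g. the heavy tail of
#' the polysemy distribution. Use [attribute_tail()] to select the top-k
#' words of an attribute.
#'
#' @param M a `multiplex` object.
#' @param words non-empty character vector of words to reshuffle among
#'   themselves.
#' @param seed integer seed.
#' @return a relabelled `multiplex`.
#' @export
targeted_full_reshuffle <- function(M, words, seed = NULL) {
  if (!length(words)) stop("'words' must be non-empty")
  full_reshuffle(M, seed = seed, subset = words)
}

#' Top-k tail of an attribute
#'
#' Helper selecting the k words with the largest (or smallest) values of an
#' attribute, the construction used to pick e.g. high-polysemy words for
#' targeted reshuffling.
#'
#' @param attrs a [word_attributes()] table.
#' @param attribute attribute column name.
#' @param k number of words.
#' @param decreasing take the largest values (default) or the smallest.
#' @return character vector of k words.
#' @export
attribute_tail <- function(attrs, attribute, k, decreasing = TRUE) {
  if (!attribute %in% names(attrs))
    stop(sprintf("unknown attribute '%s'", attribute))
  o <- order(attrs[[attribute]], decreasing = decreasing)
  attrs$word[o[seq_len(min(k, nrow(attrs)))]]
}

#' Per-layer label perturbation
#'
#' Mimics small annotation errors: on each layer independently, a uniformly
#' chosen set of `ceiling(per_layer_fraction * N)` words has its labels
#' permuted among themselves. Each layer remains isomorphic to its original.
#'
#' @param M a `multiplex` object.
#' @param per_layer_fraction fraction of words perturbed per layer, `[0, 1]`.
#' @param seed integer seed.
#' @return a perturbed `multiplex`.
#' @export
label_perturbation <- function(M, per_layer_fraction, seed = NULL) {
  if (per_layer_fraction < 0 || per_layer_fraction > 1)
    stop("'per_layer_fraction' must lie in [0, 1]")
  n <- length(M$nodes)
  k <- ceiling(per_layer_fraction * n)
  if (k == 0L) return(M)
  with_seed(seed, {
    edges <- lapply(M$edges, function(e) {
      chosen <- sample.int(n, k)
      perm <- seq_len(n)
      perm[chosen] <- chosen[sample.int(k)]
      canonical_edges(perm[e[, 1]], perm[e[, 2]])
    })
    structure(list(nodes = M$nodes, layers = M$layers, edges = edges),
              class = "multiplex")
  })
}

#' Partial reshuffling of node attributes
#'
#' Keeps the topology fixed and permutes the values of the named attribute
#' columns across words. By default each named attribute is permuted
#' independently; `joint = TRUE` applies one common permutation to all named
#' columns, preserving their mutual dependence while still destroying the
#' correlation with the topology.
#'
#' @param attrs a [word_attributes()] table.
#' @param attributes character vector of attribute column names to reshuffle.
#' @param seed integer seed.
#' @param joint permute the named columns as a tuple rather than
#'   independently.
#' @return a [word_attributes()] table with permuted columns.
#' @export
partial_reshuffle <- function(attrs, attributes, seed = NULL, joint = FALSE) {
  unknown <- setdiff(attributes, setdiff(names(attrs), "word"))
  if (length(unknown))
    stop(sprintf("unknown attribute(s): %s", paste(unknown, collapse = ", ")))
  if (!length(attributes)) return(attrs)
  n <- nrow(attrs)
  with_seed(seed, {
    if (joint) {
      p <- sample.int(n)
      for (a in attributes) attrs[[a]] <- attrs[[a]][p]
    } else {
      for (a in attributes) attrs[[a]] <- attrs[[a]][sample.int(n)]
    }
    attrs
  })
}

#' Persistence of LVC membership under rewiring
#'
#' Quantifies the robustness of the largest viable cluster to link noise:
#' repeatedly rewire a fraction of intra-layer links with
#' [configuration_rewire()], re-detect the LVC, and record the percentage of
#' original LVC members still inside the new LVC.
#'
#' @param M a `multiplex` object with a non-trivial LVC.
#' @param rewire_fraction fraction of links displaced per repetition.
#' @param repetitions number of independent rewirings.
#' @param seed master seed.
#' @return list with `mean`, `sd` (percentages) and the per-repetition
#'   `persistence` vector.
#' @export
lvc_persistence <- function(M, rewire_fraction, repetitions = 50,
                            seed = NULL) {
  lvc0 <- largest_viable_cluster(M)$members
  if (!length(lvc0)) stop("original network has no non-trivial LVC")
  seeds <- derive_seeds(seed, repetitions)
  persistence <- vapply(seeds, function(s) {
    Mr <- configuration_rewire(M, rewire_fraction, seed = s)
    lvc1 <- largest_viable_cluster(Mr)$members
    100 * length(intersect(lvc0, lvc1)) / length(lvc0)
  }, 0)
  list(mean = mean(persistence),
       sd = if (repetitions > 1) stats::sd(persistence) else 0,
       persistence = persistence)
}
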