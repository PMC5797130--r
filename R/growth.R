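#' Internal: evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's random stream. A `NULL` seed leaves the stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic per-iteration seeds below 2^31 derived from a master seed
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

new_ordering <- function(sequence, scheme, seed = NULL) {
  structure(list(sequence = as.character(sequence), scheme = scheme,
                 seed = seed),
            class = "acquisition_ordering")
}

#' @export
print.acquisition_ordering <- function(x, ...) {
  cat(sprintf("acquisition ordering (%s): %d words\n",
              x$scheme, length(x$sequence)))
  invisible(x)
}

#' Smeared age-of-acquisition ordering
#'
#' Normative acquisition orderings account for individual variability in the
#' age at which a word is learned by resampling ("smearing") each word's age
#' of acquisition from a Gaussian with that word's reported mean and standard
#' deviation, then sorting words by the sampled age. Sampled ages are used
#' for ordering only and are deliberately not clamped to positive values:
#' truncation would bias the earliest ranks.
#'
#' @param attrs a [word_attributes()] table with complete `aoa_mean` and
#'   `aoa_sd` columns.
#' @param seed integer seed for the Gaussian draws (`NULL` = current stream).
#' @return an `acquisition_ordering` (fields `sequence`, `scheme`, `seed`).
#' @export
smear_aoa <- function(attrs, seed = NULL) {
  miss <- is.na(attrs$aoa_mean) | is.na(attrs$aoa_sd)
  if (any(miss))
    stop(sprintf("missing AoA fields for: %s",
                 paste(utils::head(attrs$word[miss], 5), collapse = ", ")))
  ages <- with_seed(seed, stats::rnorm(nrow(attrs), attrs$aoa_mean, attrs$aoa_sd))
  new_ordering(attrs$word[order(ages)], "aoa_smeared", seed)
}

#' Attribute-based acquisition ordering
#'
#' Orders words by a psycholinguistic attribute or by multidegree, the
#' acquisition schemes used as comparisons for normative (age-of-acquisition)
#' growth. Default directions follow the acquisition hypotheses: frequency,
#' polysemy, multidegree and concreteness descending (words richer in the
#' attribute are learned earlier), length and reaction time ascending,
#' `random` a uniform shuffle. Tied words are permuted uniformly at random
#' under `seed`, so that ensembles over seeds average over tie orderings.
#'
#' @param key one of `"frequency"`, `"polysemy"`, `"length"`,
#'   `"concreteness"`, `"reaction_time"`, `"multidegree"`, `"random"`.
#' @param attrs a [word_attributes()] table (required for attribute keys).
#' @param M a `multiplex` object (required for `key = "multidegree"`, and
#'   for `key = "random"` when `attrs` is absent).
#' @param direction `"auto"` (scheme default), `"ascending"` or
#'   `"descending"`.
#' @param seed integer seed controlling tie-breaking / shuffling.
#' @return an `acquisition_ordering`.
#' @export
attribute_ordering <- function(key, attrs = NULL, M = NULL,
                               direction = c("auto", "ascending", "descending"),
                               seed = NULL) {
  direction <- match.arg(direction)
  keys_desc <- c("frequency", "polysemy", "multidegree", "concreteness")
  keys_asc <- c("length", "reaction_time")
  if (!key %in% c(keys_desc, keys_asc, "random"))
    stop(sprintf("unknown ordering key '%s'", key))

  if (key == "random") {
    words <- if (!is.null(attrs)) attrs$word else if (!is.null(M)) M$nodes
      else stop("'attrs' or 'M' required")
    seq <- with_seed(seed, sample(words))
    return(new_ordering(seq, "random", seed))
  }
  if (key == "multidegree") {
    if (is.null(M)) stop("'M' required for multidegree ordering")
    vals <- multidegree(M)
    words <- M$nodes
  } else {
    if (is.null(attrs)) stop("'attrs' required for attribute orderings")
    vals <- attrs[[key]]
    words <- attrs$word
    if (anyNA(vals))
      stop(sprintf("missing '%s' values for: %s", key,
                   paste(utils::head(words[is.na(vals)], 5), collapse = ", ")))
  }
  decreasing <- switch(direction,
                       auto = key %in% keys_desc,
                       ascending = FALSE,
                       descending = TRUE)
  tie_break <- with_seed(seed, stats::runif(length(vals)))
  o <- order(if (decreasing) -as.numeric(vals) else as.numeric(vals), tie_break)
  new_ordering(words[o], key, seed)
}

#' Developmental timeline from mean ages of acquisition
#'
#' Maps "number of words acquired" to a developmental stage in years using
#' the non-smeared mean age-of-acquisition ranking: `t(n)` is the n-th
#' smallest mean AoA, so that e.g. the first thousand acquired words span the
#' ages at which the thousand earliest-learned words are typically acquired.
#'
#' @param attrs a [word_attributes()] table.
#' @return numeric vector `t(n)` of length `nrow(attrs)` (years).
#' @export
aoa_timeline <- function(attrs) {
  if (anyNA(attrs$aoa_mean)) stop("aoa_mean must be complete")
  sort(attrs$aoa_mean)
}

#' Growth trajectory of the largest viable cluster
#'
#' Simulates lexicon growth: words are added one at a time following an
#' acquisition ordering, and after each addition the size of the largest
#' non-trivial viable cluster of the induced subnetwork on the acquired
#' prefix is recorded.
#'
#' The default engine is incremental: adding one word can only create or
#' merge viable clusters containing that word (connectivity among previously
#' present words is untouched), so only the refinement fixpoint around the
#' new word needs recomputing. `method = "from_scratch"` re-detects all
#' clusters of every prefix with [maximal_viable_clusters()]; both methods
#' return identical trajectories and the equality is asserted in the test
#' suite.
#'
#' @param M a `multiplex` object.
#' @param ordering an `acquisition_ordering` covering exactly `M$nodes`.
#' @param attrs optional [word_attributes()] used to attach the
#'   developmental timeline ([aoa_timeline()]) to the trajectory.
#' @param method `"incremental"` or `"from_scratch"`.
#' @param track_attribute optional name of an attribute column; the mean of
#'   that attribute over current LVC members is recorded per step.
#' @return a `growth_trajectory`: data frame with columns `n`, `word`, `age`
#'   (NA without `attrs`), `lvc_size`, and `attr_mean` when tracked.
#' @export
growth_trajectory <- function(M, ordering, attrs = NULL,
                              method = c("incremental", "from_scratch"),
                              track_attribute = NULL) {
  method <- match.arg(method)
  words <- ordering$sequence
  if (length(words) != length(M$nodes) || !setequal(words, M$nodes))
    stop("ordering must be a permutation of the network's node set")
  attr_values <- NULL
  if (!is.null(track_attribute)) {
    if (is.null(attrs) || !track_attribute %in% names(attrs))
      stop(sprintf("unknown attribute '%s'", track_attribute))
    attr_values <- attrs[[track_attribute]][match(M$nodes, attrs$word)]
  }
  if (method == "incremental") {
    res <- viable_growth_engine(M, words, attr_values)
  } else {
    n <- length(words)
    L <- integer(n)
    A <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      sub <- induced_subnetwork(M, words[seq_len(k)])
      lvc <- largest_viable_cluster(sub)
      L[k] <- length(lvc$members)
      if (!is.null(attr_values) && L[k] > 0)
        A[k] <- mean(attr_values[match(lvc$members, M$nodes)])
    }
    res <- list(lvc_size = L, attr_mean = A)
  }
  age <- rep(NA_real_, length(words))
  if (!is.null(attrs)) age <- aoa_timeline(attrs)[seq_along(words)]
  out <- data.frame(n = seq_along(words), word = words, age = age,
                    lvc_size = res$lvc_size, stringsAsFactors = FALSE)
  if (!is.null(attr_values)) out$attr_mean <- res$attr_mean
  class(out) <- c("growth_trajectory", "data.frame")
  attr(out, "scheme") <- ordering$scheme
  out
}

## incremental engine on integer indices; returns lvc_size (and attr mean of
## the current largest non-trivial cluster) per step
viable_growth_engine <- function(M, order_words, attr_values = NULL) {
  n <- length(M$nodes)
  ord <- match(order_words, M$nodes)
  adj <- multiplex_adjacency(M)
  nl <- length(adj)
  added <- logical(n)
  cid <- integer(n)
  csize <- integer(n)
  csum <- numeric(n)
  next_id <- 0L
  best_id <- 0L
  L <- integer(n)
  A <- rep(NA_real_, n)
  track <- !is.null(attr_values)
  for (k in seq_len(n)) {
    v <- ord[k]
    added[v] <- TRUE
    viable_candidate <- TRUE
    for (l in seq_len(nl)) {
      nb <- adj[[l]][[v]]
      if (!length(nb) || !any(added[nb])) { viable_candidate <- FALSE; break }
    }
    if (viable_candidate) {
      S <- fixpoint_cluster(v, adj, added)
      sz <- sum(S)
      if (sz >= 2L) {
        mem <- which(S)
        old <- unique(cid[mem])
        old <- old[old != 0L]
        next_id <- next_id + 1L
        cid[mem] <- next_id
        csize[next_id] <- sz
        if (track) csum[next_id] <- sum(attr_values[mem])
        if (length(old)) csize[old] <- 0L
        if (sz > 2L && (best_id == 0L || sz >= csize[best_id]))
          best_id <- next_id
      }
    }
    if (best_id > 0L && csize[best_id] == 0L) {
      ## previous best was absorbed; its absorber is at least as large
      best_id <- which.max(csize)
    }
    L[k] <- if (best_id > 0L) csize[best_id] else 0L
    if (track && best_id > 0L) A[k] <- csum[best_id] / csize[best_id]
  }
  list(lvc_size = L, attr_mean = A)
}

## maximal viable cluster containing v within the node mask 'added'
fixpoint_cluster <- function(v, adj, added) {
  S <- bfs_component(v, adj[[1]], added)
  size <- sum(S)
  if (size == 1L) return(S)
  repeat {
    changed <- FALSE
    for (l in seq_along(adj)) {
      S2 <- bfs_component(v, adj[[l]], S)
      s2 <- sum(S2)
      if (s2 < size) {
        S <- S2
        size <- s2
        changed <- TRUE
        if (size == 1L) return(S)
      }
    }
    if (!changed) return(S)
  }
}

#' Detect an explosive transition in a growth trajectory
#'
#' Scans the LVC-size series for the first single-step jump strictly greater
#' than the discontinuity threshold (default 10 words, with `L(0) = 0`). If
#' no such jump exists the trajectory is non-explosive and the emergence
#' index falls back to the first step at which a non-trivial cluster exists.
#' The summary reports both the single-step jump and the LVC size right
#' after emergence; the two coincide when the cluster appears out of nothing.
#'
#' @param trajectory a [growth_trajectory()].
#' @param threshold discontinuity threshold in words; a jump must strictly
#'   exceed it to count as explosive.
#' @param all_jumps also return every super-threshold jump (data frame
#'   `n`, `age`, `jump`), capturing e.g. second explosive transitions.
#' @return a `transition_summary`: list with `explosive`, `emergence_index`,
#'   `emergence_age`, `jump`, `lvc_size_at_emergence`, `critical_word`, and
#'   optionally `jumps`.
#' @export
detect_transition <- function(trajectory, threshold = 10, all_jumps = FALSE) {
  L <- trajectory$lvc_size
  if (!length(L)) stop("empty trajectory")
  d <- diff(c(0L, L))
  expl <- which(d > threshold)
  if (length(expl)) {
    n_star <- expl[1]
    out <- list(explosive = TRUE,
                emergence_index = n_star,
                emergence_age = trajectory$age[n_star],
                jump = d[n_star],
                lvc_size_at_emergence = L[n_star],
                critical_word = trajectory$word[n_star])
  } else {
    n_star <- which(L > 2)[1]
    out <- list(explosive = FALSE,
                emergence_index = n_star,
                emergence_age = if (is.na(n_star)) NA_real_ else trajectory$age[n_star],
                jump = if (is.na(n_star)) NA_real_ else d[n_star],
                lvc_size_at_emergence = if (is.na(n_star)) NA_integer_ else L[n_star],
                critical_word = if (is.na(n_star)) NA_character_ else trajectory$word[n_star])
  }
  if (all_jumps)
    out$jumps <- data.frame(n = expl, age = trajectory$age[expl], jump = d[expl])
  class(out) <- "transition_summary"
  out
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("transition: %s, emergence at n = %s (age %s), jump %s words\n",
              if (isTRUE(x$explosive)) "explosive" else "gradual",
              x$emergence_index, signif(x$emergence_age, 3), x$jump))
  invisible(x)
}

#' Critical word of a growth trajectory
#'
#' The critical word is the single word whose addition triggers the sudden
#' emergence of the LVC: the word acquired at the first super-threshold jump.
#' Non-explosive trajectories have no critical word.
#'
#' @param M a `multiplex` object.
#' @param ordering an `acquisition_ordering`.
#' @param attrs optional attributes for the timeline.
#' @param threshold discontinuity threshold in words.
#' @return the critical word (character) or `NA_character_`.
#' @export
critical_word <- function(M, ordering, attrs = NULL, threshold = 10) {
  tr <- growth_trajectory(M, ordering, attrs = attrs)
  ts <- detect_transition(tr, threshold = threshold)
  if (!isTRUE(ts$explosive)) return(NA_character_)
  ts$critical_word
}

#' Ensemble of growth transitions
#'
#' Repeats the growth experiment over an ensemble of acquisition orderings
#' (e.g. independent smears of the age-of-acquisition ratings, or independent
#' tie reshufflings of an attribute ranking) and summarises the explosive
#' behaviour: the fraction of iterations with a discontinuity, and the
#' magnitude of the transition. Transition magnitudes are averaged over
#' explosive iterations only; the count of explosive iterations is reported
#' alongside.
#'
#' @param M a `multiplex` object.
#' @param ordering_factory function taking an integer seed and returning an
#'   `acquisition_ordering` (see e.g. `function(s) smear_aoa(attrs, s)`).
#' @param iterations ensemble size.
#' @param threshold discontinuity threshold in words.
#' @param attrs optional attributes for the developmental timeline.
#' @param seed master seed; per-iteration seeds are derived from it
#'   deterministically.
#' @return a `transition_ensemble`: list with `chi` (fraction explosive),
#'   `delta_L_mean`, `delta_L_sd` (words, over explosive iterations),
#'   `emergence_ages`, `emergence_indices`, `jumps`, `critical_words`,
#'   `n_explosive`, `iterations`.
#' @export
ensemble_transitions <- function(M, ordering_factory, iterations = 200,
                                 threshold = 10, attrs = NULL, seed = NULL) {
  if (iterations < 1) stop("iterations must be >= 1")
  seeds <- derive_seeds(seed, iterations)
  summaries <- lapply(seeds, function(s) {
    tr <- growth_trajectory(M, ordering_factory(s), attrs = attrs)
    detect_transition(tr, threshold = threshold)
  })
  expl <- vapply(summaries, function(x) isTRUE(x$explosive), TRUE)
  jumps <- vapply(summaries, function(x) as.numeric(x$jump), 0)
  out <- list(chi = mean(expl),
              delta_L_mean = if (any(expl)) mean(jumps[expl]) else NA_real_,
              delta_L_sd = if (sum(expl) > 1) stats::sd(jumps[expl]) else
                if (any(expl)) 0 else NA_real_,
              emergence_ages = vapply(summaries, function(x)
                as.numeric(x$emergence_age), 0),
              emergence_indices = vapply(summaries, function(x)
                as.numeric(x$emergence_index), 0),
              jumps = jumps,
              critical_words = vapply(summaries, function(x)
                as.character(x$critical_word), ""),
              n_explosive = sum(expl),
              iterations = iterations)
  class(out) <- "transition_ensemble"
  out
}

#' @export
print.transition_ensemble <- function(x, ...) {
  cat(sprintf(
    "transition ensemble (%d iterations): chi = %.2f, deltaL = %.1f +- %.1f words\n",
    x$iterations, x$chi,
    if (is.na(x$delta_L_mean)) NA_real_ else x$delta_L_mean,
    if (is.na(x$delta_L_sd)) NA_real_ else x$delta_L_sd))
  invisible(x)
}

#' Overlapping coefficient of two samples
#'
#' Histogram overlap of two empirical distributions, normalised by the
#' maximum overlap attainable when translating the location of the second
#' sample. The raw overlap is `sum(min(p_i, q_i))` over a shared equal-width
#' binning; the denominator is the maximum raw overlap over a uniform grid of
#' location shifts of the second sample spanning plus/minus the pooled range.
#' 100 percent means one distribution is fully contained in the other; 0
#' percent means the distributions share no bin.
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @param bins number of bins over the pooled range, or `NULL` for a
#'   Freedman-Diaconis bin width computed on the pooled sample.
#' @param shift_steps size of the shift grid (includes the zero shift).
#' @return overlap percentage in `[0, 100]`.
#' @export
overlapping_coefficient <- function(sample_a, sample_b, bins = NULL,
                                    shift_steps = 201) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  pooled <- c(a, b)
  rng <- range(pooled)
  if (is.null(bins)) {
    h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
    if (!is.finite(h) || h <= 0) {
      if (diff(rng) <= 0) stop("degenerate binning: pooled sample has no spread")
      h <- diff(rng) / ceiling(log2(length(pooled)) + 1)  # Sturges fallback
    }
  } else {
    if (bins < 1 || diff(rng) <= 0) stop("degenerate binning")
    h <- diff(rng) / bins
  }
  x0 <- rng[1]
  binned <- function(x) {
    idx <- floor((x - x0) / h)
    tab <- table(idx) / length(x)
    tab
  }
  overlap_at <- function(shift) {
    pa <- binned(a); pb <- binned(b + shift)
    common <- intersect(names(pa), names(pb))
    if (!length(common)) return(0)
    sum(pmin(as.numeric(pa[common]), as.numeric(pb[common])))
  }
  shifts <- seq(-diff(rng), diff(rng), length.out = shift_steps)
  shifts <- sort(unique(c(0, shifts)))
  denom <- max(vapply(shifts, overlap_at, 0))
  if (denom <= 0) return(0)
  100 * overlap_at(0) / denom
}

#' Attribute time series of the growing LVC
#'
#' For each acquisition step, the mean of a psycholinguistic attribute over
#' the words currently inside the LVC, averaged over an ensemble of
#' orderings and rescaled to `[0, 1]` by the curve's maximum. Steps at which
#' no non-trivial cluster exists in any iteration are reported as missing.
#'
#' @param M a `multiplex` object.
#' @param ordering_factory function from integer seed to ordering.
#' @param attrs a [word_attributes()] table.
#' @param attribute attribute column name to track.
#' @param iterations ensemble size.
#' @param seed master seed.
#' @return data frame with columns `n` and `value` (max-rescaled mean).
#' @export
lvc_attribute_timeseries <- function(M, ordering_factory, attrs, attribute,
                                     iterations = 200, seed = NULL) {
  if (!attribute %in% names(attrs))
    stop(sprintf("unknown attribute '%s'", attribute))
  seeds <- derive_seeds(seed, iterations)
  acc <- matrix(NA_real_, nrow = length(M$nodes), ncol = iterations)
  for (i in seq_len(iterations)) {
    tr <- growth_trajectory(M, ordering_factory(seeds[i]), attrs = attrs,
                            track_attribute = attribute)
    acc[, i] <- tr$attr_mean
  }
  value <- rowMeans(acc, na.rm = TRUE)
  value[is.nan(value)] <- NA_real_
  mx <- suppressWarnings(max(value, na.rm = TRUE))
  if (is.finite(mx) && mx != 0) value <- value / mx
  data.frame(n = seq_len(length(M$nodes)), value = value)
}
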