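#' Monte Carlo sample-size corrected statistic
#'
#' Group statistics compared across groups of unequal size are corrected by
#' subsampling: the statistic (median, or mean for heavy-tailed attributes)
#' is evaluated on repeated uniform without-replacement subsamples of a
#' common target size, and the mean over repetitions is reported with the
#' standard deviation over repetitions as its error.
#'
#' @param values numeric sample (NAs dropped).
#' @param target_n subsample size, at most `length(values)`.
#' @param kind `"median"` or `"mean"`.
#' @param repetitions number of Monte Carlo subsamples.
#' @param seed integer seed.
#' @return list with `estimate`, `error` (sd over repetitions), `kind`,
#'   `target_n`, `repetitions`.
#' @export
sample_size_corrected_stat <- function(values, target_n,
                                       kind = c("median", "mean"),
                                       repetitions = 1000, seed = NULL) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (target_n > length(values)) stop("target_n exceeds sample size")
  if (repetitions < 1) stop("repetitions must be >= 1")
  stat <- if (kind == "median") stats::median else mean
  if (target_n == length(values)) {
    return(list(estimate = stat(values), error = 0, kind = kind,
                target_n = target_n, repetitions = repetitions))
  }
  draws <- with_seed(seed, vapply(seq_len(repetitions), function(i)
    stat(values[sample.int(length(values), target_n)]), 0))
  list(estimate = mean(draws),
       error = if (repetitions > 1) stats::sd(draws) else 0,
       kind = kind, target_n = target_n, repetitions = repetitions)
}

#' Degree-corrected matched sample
#'
#' For each word of an in-group sample, picks a distinct out-group word with
#' the same multidegree, so that group comparisons are not confounded by the
#' in-group's higher connectivity. When no exact match remains the nearest
#' available multidegree is used and counted as a mismatch.
#'
#' @param M a `multiplex` object.
#' @param in_set character vector of in-group words (e.g. LVC members).
#' @param out_pool character vector of candidate out-group words, disjoint
#'   from `in_set`.
#' @param seed integer seed (matching order and tie choices).
#' @return list with `matched` (character, same length as `in_set`),
#'   `mismatches` (count of inexact matches) and `max_degree_gap`.
#' @export
degree_corrected_sample <- function(M, in_set, out_pool, seed = NULL) {
  if (!length(out_pool)) stop("empty out-group pool")
  if (length(intersect(in_set, out_pool)))
    stop("in_set and out_pool must be disjoint")
  if (length(out_pool) < length(in_set))
    stop("out-group pool smaller than in-group sample")
  deg <- multidegree(M)
  deg_in <- deg[match(in_set, M$nodes)]
  deg_pool <- deg[match(out_pool, M$nodes)]
  if (anyNA(deg_in) || anyNA(deg_pool)) stop("unknown words in inputs")
  with_seed(seed, {
    avail <- rep(TRUE, length(out_pool))
    matched <- character(length(in_set))
    mismatches <- 0L
    gaps <- integer(length(in_set))
    for (k in sample.int(length(in_set))) {  # random matching order
      gap <- abs(deg_pool - deg_in[k])
      gap[!avail] <- NA
      best <- min(gap, na.rm = TRUE)
      cand <- which(avail & gap == best)
      pick <- if (length(cand) > 1L) sample(cand, 1L) else cand
      matched[k] <- out_pool[pick]
      avail[pick] <- FALSE
      gaps[k] <- best
      if (best > 0L) mismatches <- mismatches + 1L
    }
    list(matched = matched, mismatches = mismatches,
         max_degree_gap = max(gaps))
  })
}

#' Psycholinguistic group comparison
#'
#' Compares word attributes between two word groups (typically LVC-in versus
#' LVC-out words). Heavy-tailed attributes (frequency, polysemy) are
#' summarised by the mean, all others by the median; frequency is reported as
#' the base-10 logarithm of the raw counts. Both groups are Monte Carlo
#' sample-size corrected to the smaller group's size; optionally the
#' out-group is first degree-matched to the in-group.
#'
#' @param attrs a [word_attributes()] table.
#' @param in_set,out_set non-empty character vectors of words.
#' @param repetitions Monte Carlo repetitions.
#' @param seed integer seed.
#' @param degree_corrected match the out-group by multidegree first
#'   (requires `M`).
#' @param M a `multiplex` object (only used for degree correction).
#' @param attributes attribute columns to compare.
#' @return a `group_comparison` data frame: one row per attribute with the
#'   in/out statistics, their errors, the statistic kind and sample sizes.
#' @export
compare_groups <- function(attrs, in_set, out_set, repetitions = 1000,
                           seed = NULL, degree_corrected = FALSE, M = NULL,
                           attributes = c("aoa_mean", "concreteness",
                                          "reaction_time", "frequency",
                                          "polysemy", "length")) {
  if (!length(in_set) || !length(out_set)) stop("both groups must be non-empty")
  seeds <- derive_seeds(seed, 2L + length(attributes) * 2L)
  if (degree_corrected) {
    if (is.null(M)) stop("degree correction requires 'M'")
    pool <- setdiff(out_set, in_set)
    match_seeds <- derive_seeds(seeds[1], 2L)
    ## when the in-group outnumbers the pool, match a random in-subsample of
    ## the pool's size; the comparison is subsampled to that size anyway
    in_match <- if (length(in_set) > length(pool))
      with_seed(match_seeds[1], sample(in_set, length(pool))) else in_set
    dm <- degree_corrected_sample(M, in_match, pool, seed = match_seeds[2])
    in_set <- in_match
    out_set <- dm$matched
  }
  heavy <- c("frequency", "polysemy")
  target_n <- min(length(in_set), length(out_set))
  rows <- lapply(seq_along(attributes), function(ai) {
    a <- attributes[ai]
    if (!a %in% names(attrs)) stop(sprintf("unknown attribute '%s'", a))
    value_of <- function(words) {
      v <- attrs[[a]][match(words, attrs$word)]
      if (a == "frequency") v <- log10(pmax(v, 1))
      v
    }
    kind <- if (a %in% heavy) "mean" else "median"
    s_in <- sample_size_corrected_stat(value_of(in_set), target_n, kind,
                                       repetitions, seed = seeds[2L * ai])
    s_out <- sample_size_corrected_stat(value_of(out_set), target_n, kind,
                                        repetitions, seed = seeds[2L * ai + 1L])
    data.frame(attribute = if (a == "frequency") "log_frequency" else a,
               statistic = kind,
               in_value = s_in$estimate, in_error = s_in$error,
               out_value = s_out$estimate, out_error = s_out$error,
               n_in = length(in_set), n_out = length(out_set),
               target_n = target_n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Exact binomial sign test
#'
#' Tests whether paired differences are symmetrically distributed around
#' zero: zero differences are dropped and the count of positive signs is
#' referred to a Binomial(n, 1/2).
#'
#' @param differences numeric vector of paired differences.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `p_value`, `n_nonzero`, `n_positive`.
#' @export
sign_test <- function(differences,
                      alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- differences[!is.na(differences) & differences != 0]
  if (!length(d)) stop("all differences are zero or missing")
  k <- sum(d > 0)
  n <- length(d)
  p <- stats::binom.test(k, n, p = 0.5, alternative = alternative)$p.value
  list(p_value = p, n_nonzero = n, n_positive = k)
}

#' Tie-corrected Kendall rank correlation
#'
#' Kendall's tau-b between two numeric sequences, the rank-correlation
#' measure used throughout for attribute/age-of-acquisition associations.
#' Constant inputs have undefined rank correlation and raise an error.
#'
#' @param x,y numeric vectors of equal length (pairs with NAs are dropped).
#' @return tau in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rank correlation undefined for constant input")
  unname(stats::cor(x, y, method = "kendall"))
}

#' Cumulative attribute curve
#'
#' Empirical cumulative probability of finding a word in a group whose
#' attribute value is at most a threshold, for a vector of thresholds.
#' Concreteness ratings are min-max renormalised to `[0, 1]` (over the full
#' attribute table) before evaluation, matching the convention for reporting
#' concreteness on a common scale.
#'
#' @param attrs a [word_attributes()] table.
#' @param attribute attribute column name.
#' @param group character vector of words to evaluate (default: all).
#' @param thresholds numeric vector of thresholds T.
#' @return data frame with columns `threshold` and `probability`.
#' @export
cumulative_curve <- function(attrs, attribute, group = NULL, thresholds) {
  if (!attribute %in% names(attrs))
    stop(sprintf("unknown attribute '%s'", attribute))
  vals_all <- attrs[[attribute]]
  if (attribute == "concreteness") {
    rng <- range(vals_all, na.rm = TRUE)
    if (diff(rng) > 0) vals_all <- (vals_all - rng[1]) / diff(rng)
  }
  if (is.null(group)) {
    v <- vals_all
  } else {
    idx <- match(as.character(group), attrs$word)
    if (anyNA(idx)) stop("unknown words in group")
    v <- vals_all[idx]
  }
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty group after dropping missing values")
  probability <- vapply(thresholds, function(T) mean(v <= T), 0)
  data.frame(threshold = thresholds, probability = probability)
}

#' Core-periphery link densities
#'
#' Classifies every layer's links by the membership of their endpoints in a
#' core set (e.g. the LVC): core-core (In/In), boundary (In/Out) and
#' periphery (Out/Out). Counts are turned into pair-normalised densities by
#' dividing by the number of available node pairs of each class, and the
#' density matrix is additionally normalised by its global maximum. A
#' core-periphery structure manifests as
#' `p_In/In > p_In/Out > p_Out/Out` on every layer.
#'
#' @param M a `multiplex` object.
#' @param core non-empty proper subset of `M$nodes`.
#' @return a `core_periphery_densities` list with per-layer data frames of
#'   `counts` and `densities`, and the max-normalised density matrix
#'   `normalised` (layers by classes).
#' @export
core_periphery_densities <- function(M, core) {
  core <- as.character(core)
  idx <- match(core, M$nodes)
  if (anyNA(idx)) stop("unknown words in core")
  n <- length(M$nodes)
  n_in <- length(idx)
  if (n_in == 0L || n_in == n) stop("core must be a non-empty proper subset")
  in_core <- logical(n); in_core[idx] <- TRUE
  n_out <- n - n_in
  pairs <- c(in_in = n_in * (n_in - 1) / 2,
             in_out = as.numeric(n_in) * n_out,
             out_out = n_out * (n_out - 1) / 2)
  counts <- t(vapply(M$layers, function(ln) {
    e <- M$edges[[ln]]
    a <- in_core[e[, 1]]; b <- in_core[e[, 2]]
    c(in_in = sum(a & b), in_out = sum(xor(a, b)), out_out = sum(!a & !b))
  }, c(in_in = 0, in_out = 0, out_out = 0)))
  dens <- sweep(counts, 2, pairs, "/")
  stopifnot(all(rowSums(counts) ==
                  vapply(M$edges, nrow, 0L)))  # classification conserves totals
  structure(list(counts = as.data.frame(counts),
                 densities = as.data.frame(dens),
                 normalised = dens / max(dens),
                 n_in = n_in, n_out = n_out),
            class = "core_periphery_densities")
}

#' @export
print.core_periphery_densities <- function(x, ...) {
  cat(sprintf("core-periphery densities (%d core, %d periphery words)\n",
              x$n_in, x$n_out))
  print(round(x$densities, 6))
  invisible(x)
}
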