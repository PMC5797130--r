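make_attrs <- function(words, aoa, sd = 0, frequency = NULL) {
  n <- length(words)
  word_attributes(data.frame(
    word = words, aoa_mean = aoa, aoa_sd = rep(sd, length.out = n),
    frequency = if (is.null(frequency)) rev(seq_len(n)) else frequency,
    polysemy = rep(2, n), concreteness = rep(3, n),
    reaction_time = rep(600, n), length = rep(4, n),
    stringsAsFactors = FALSE))
}

test_that("smearing with zero variance reproduces the mean-AoA ranking", {
  at <- make_attrs(letters[1:6], aoa = c(3, 1, 5, 2, 6, 4), sd = 0)
  o <- smear_aoa(at, seed = 1)
  expect_equal(o$sequence, letters[1:6][order(at$aoa_mean)])
  expect_equal(smear_aoa(make_attrs("solo", 4))$sequence, "solo")
  at$aoa_sd[2] <- NA
  expect_error(smear_aoa(at), "missing AoA")
})

test_that("smearing inversion probability matches the Gaussian closed form", {
  ## words a ~ N(5,1), b ~ N(6,1): P(b before a) = pnorm(-1/sqrt(2))
  at <- make_attrs(c("a", "b"), aoa = c(5, 6), sd = 1)
  n_draws <- 1e5
  set.seed(99)
  inversions <- sum(vapply(seq_len(n_draws), function(i)
    smear_aoa(at)$sequence[1] == "b", TRUE))
  expect_equal(inversions / n_draws, stats::pnorm(-1 / sqrt(2)),
               tolerance = 0.01 / stats::pnorm(-1 / sqrt(2)))
})

test_that("attribute orderings sort by key with seeded uniform tie-breaking", {
  at <- make_attrs(c("x", "y", "z"), aoa = 1:3, frequency = c(3, 2, 1))
  expect_equal(attribute_ordering("frequency", at)$sequence, c("x", "y", "z"))

  at2 <- make_attrs(letters[1:5], aoa = 1:5, frequency = rep(7, 5))
  o1 <- attribute_ordering("frequency", at2, seed = 4)
  o2 <- attribute_ordering("frequency", at2, seed = 4)
  expect_identical(o1$sequence, o2$sequence)

  ## tie group of 3 among distinct values: permutations uniform over seeds
  at3 <- make_attrs(c("hi", "t1", "t2", "t3", "lo"), aoa = 1:5,
                    frequency = c(9, 5, 5, 5, 1))
  seqs <- vapply(1:1200, function(s)
    paste(attribute_ordering("frequency", at3, seed = s)$sequence,
          collapse = ""), "")
  expect_true(all(startsWith(seqs, "hi") & endsWith(seqs, "lo")))
  tab <- table(substr(seqs, 3, 8))
  expect_length(tab, 6)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)

  expect_error(attribute_ordering("colour", at), "unknown ordering key")
  expect_error(attribute_ordering("multidegree", at), "'M' required")
})

test_that("length and reaction time order ascending, others descending", {
  at <- make_attrs(c("a", "b"), aoa = 1:2)
  at$length <- c(9, 2); at$reaction_time <- c(700, 500)
  at$polysemy <- c(1, 8); at$concreteness <- c(2, 4)
  expect_equal(attribute_ordering("length", at)$sequence, c("b", "a"))
  expect_equal(attribute_ordering("reaction_time", at)$sequence, c("b", "a"))
  expect_equal(attribute_ordering("polysemy", at)$sequence, c("b", "a"))
  expect_equal(attribute_ordering("concreteness", at)$sequence, c("b", "a"))
  expect_equal(attribute_ordering("length", at,
                                  direction = "descending")$sequence,
               c("a", "b"))
})

test_that("growth trajectories are monotone and end at the full-network LVC", {
  fx <- reference_fixture()
  for (s in 1:3) {
    o <- attribute_ordering("random", M = fx$network, seed = s)
    tr <- growth_trajectory(fx$network, o)
    expect_true(all(diff(tr$lvc_size) >= 0))
    expect_true(all(tr$lvc_size <= tr$n))
    expect_equal(tr$lvc_size[nrow(tr)],
                 length(largest_viable_cluster(fx$network)$members))
  }
  expect_error(growth_trajectory(fx$network,
                                 new_ordering_for_test(fx$network$nodes[-1])),
               "permutation")
})

test_that("scheduling LVC members last keeps the LVC empty until completion", {
  fx <- reference_fixture()
  ord <- new_ordering_for_test(c(setdiff(fx$network$nodes, fx$lvc_members),
                                 fx$lvc_members))
  tr <- growth_trajectory(fx$network, ord)
  n_out <- 60 - length(fx$lvc_members)
  expect_true(all(tr$lvc_size[seq_len(n_out)] == 0))
  expect_gt(tr$lvc_size[60], 2)
})

test_that("incremental growth equals from-scratch re-detection", {
  fx <- reference_fixture()
  for (s in 1:4) {
    o <- attribute_ordering("random", M = fx$network, seed = 40 + s)
    inc <- growth_trajectory(fx$network, o)$lvc_size
    scr <- growth_trajectory(fx$network, o, method = "from_scratch")$lvc_size
    expect_identical(inc, scr)
  }
  ## also on a denser correlated instance where merges actually happen
  M <- random_test_multiplex(25, n_layers = 2, p = 0.12, seed = 8,
                             correlated = TRUE)
  o <- attribute_ordering("random", M = M, seed = 2)
  expect_identical(growth_trajectory(M, o)$lvc_size,
                   growth_trajectory(M, o, method = "from_scratch")$lvc_size)
})

test_that("transition detection applies a strict threshold and flat-tail invariance", {
  mk <- function(L) {
    structure(data.frame(n = seq_along(L), word = sprintf("w%03d", seq_along(L)),
                         age = seq_along(L) / 10, lvc_size = L),
              class = c("growth_trajectory", "data.frame"))
  }
  ## sudden appearance of a 260-word cluster with one added word
  L <- c(rep(0, 9), rep(260, 11))
  ts <- detect_transition(mk(L))
  expect_true(ts$explosive)
  expect_equal(ts$jump, 260)
  expect_equal(ts$emergence_index, 10)
  expect_equal(ts$critical_word, "w010")

  ## strictly gradual growth is not explosive
  ts2 <- detect_transition(mk(c(0, 0, 3:20)))
  expect_false(ts2$explosive)
  expect_equal(ts2$emergence_index, 3)

  ## a jump of exactly the threshold does not count (strict inequality)
  ts3 <- detect_transition(mk(c(0, 10, 10, 10)))
  expect_false(ts3$explosive)
  ts4 <- detect_transition(mk(c(0, 11, 11)))
  expect_true(ts4$explosive)

  ## appending a flat tail changes nothing
  ts5 <- detect_transition(mk(c(L, rep(260, 30))))
  expect_equal(ts5$emergence_index, ts$emergence_index)
  expect_equal(ts5$jump, ts$jump)

  ## all super-threshold jumps are reported on request
  L2 <- c(rep(0, 4), 50, 50, 50, 120, 120)
  ts6 <- detect_transition(mk(L2), all_jumps = TRUE)
  expect_equal(ts6$jumps$n, c(5, 8))
  expect_equal(ts6$jumps$jump, c(50, 70))
})

test_that("ensembles count explosive iterations and reproduce bit-exactly", {
  fx <- reference_fixture()
  at <- fx$attributes
  fac <- function(s) smear_aoa(at, s)
  ens1 <- ensemble_transitions(fx$network, fac, iterations = 20,
                               threshold = 5, attrs = at, seed = 123)
  ens2 <- ensemble_transitions(fx$network, fac, iterations = 20,
                               threshold = 5, attrs = at, seed = 123)
  expect_identical(ens1, ens2)
  expect_equal(ens1$chi, mean(ens1$jumps > 5))
  expect_equal(ens1$n_explosive, sum(ens1$jumps > 5))
  if (ens1$n_explosive > 0)
    expect_equal(ens1$delta_L_mean, mean(ens1$jumps[ens1$jumps > 5]))

  ## deterministic ordering (zero smear, no ties): chi is 0 or 1, sd zero
  at0 <- at; at0$aoa_sd <- 0
  ens0 <- ensemble_transitions(fx$network, function(s) smear_aoa(at0, s),
                               iterations = 5, threshold = 5, attrs = at0,
                               seed = 9)
  expect_true(ens0$chi %in% c(0, 1))
  expect_equal(ens0$delta_L_sd, 0)
})

test_that("critical words are completion triggers and removing them kills the jump", {
  fx <- reference_fixture()
  at0 <- fx$attributes; at0$aoa_sd <- 0
  ord <- smear_aoa(at0, 1)
  ## under the mean ordering the core completes a 9-word cluster at w09
  cw <- critical_word(fx$network, ord, threshold = 5)
  expect_equal(cw, "w09")
  expect_true(is.na(critical_word(fx$network, ord, threshold = 50)))

  ## keystone instance: the a-words are connected on layer two only through
  ## the hub, so the hub's arrival makes everything viable at once
  a <- paste0("a", 1:5)
  M <- load_multiplex(list(
    L1 = rbind(cbind(a[-5], a[-1]), c("hub", "a1")),
    L2 = cbind("hub", a)))
  late <- new_ordering_for_test(c(a, "hub"))
  tr <- growth_trajectory(M, late)
  expect_equal(tr$lvc_size, c(0, 0, 0, 0, 0, 6))
  expect_equal(critical_word(M, late, threshold = 3), "hub")

  ## with the hub first the same network grows gradually: no jump above 3
  early <- new_ordering_for_test(c("hub", a))
  tr2 <- growth_trajectory(M, early)
  expect_false(detect_transition(tr2, threshold = 3)$explosive)
  expect_equal(max(diff(c(0, tr2$lvc_size))), 3)
})

test_that("overlapping coefficient matches its closed-form anchors", {
  set.seed(31)
  x <- stats::rnorm(500)
  expect_equal(overlapping_coefficient(x, x), 100)

  near <- stats::runif(400)           # supports [0,1] vs [100,101]
  far <- stats::runif(400) + 100
  expect_equal(overlapping_coefficient(near, far), 0)

  ## N(0,1) vs N(1,1): raw overlap 2*pnorm(-1/2), shifted maximum ~ 1
  a <- stats::rnorm(30000)
  b <- stats::rnorm(30000, mean = 1)
  expect_equal(overlapping_coefficient(a, b), 100 * 2 * stats::pnorm(-0.5),
               tolerance = 2 / 61.7)

  expect_error(overlapping_coefficient(numeric(0), 1:3), "non-empty")
  expect_error(overlapping_coefficient(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("LVC attribute time series are max-rescaled with missing prefixes", {
  fx <- reference_fixture()
  at <- fx$attributes
  fac <- function(s) smear_aoa(at, s)
  ts <- lvc_attribute_timeseries(fx$network, fac, at, "reaction_time",
                                 iterations = 5, seed = 2)
  expect_equal(nrow(ts), 60)
  expect_true(all(is.na(ts$value[1:5])))       # no cluster that early
  expect_equal(max(ts$value, na.rm = TRUE), 1)
  expect_error(lvc_attribute_timeseries(fx$network, fac, at, "nope",
                                        iterations = 2),
               "unknown attribute")
})

test_that("vanishing smear converges to the deterministic mean ranking", {
  at <- make_attrs(letters[1:10], aoa = 10:1, sd = 1e-12)
  o <- smear_aoa(at, seed = 3)
  expect_equal(o$sequence, rev(letters[1:10]))
})
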