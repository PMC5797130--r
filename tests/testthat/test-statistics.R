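test_that("sample-size corrected statistics reduce to plain statistics", {
  v <- c(4, 8, 15, 16, 23, 42)
  full <- sample_size_corrected_stat(v, length(v), "median", 50, seed = 1)
  expect_equal(full$estimate, stats::median(v))
  expect_equal(full$error, 0)

  const <- sample_size_corrected_stat(rep(7, 20), 5, "mean", 100, seed = 1)
  expect_equal(const$estimate, 7)
  expect_equal(const$error, 0)

  set.seed(2)
  u <- stats::runif(5000)
  sub <- sample_size_corrected_stat(u, 1000, "median", 1000, seed = 3)
  expect_lt(abs(sub$estimate - 0.5), 3 * sub$error + 0.02)
  expect_error(sample_size_corrected_stat(u, 6000, "median"), "exceeds")
})

test_that("degree-corrected samples match multidegrees", {
  ## pool contains an exact-degree twin for every in-word
  M <- load_multiplex(list(
    L1 = rbind(c("a", "b"), c("a", "c"), c("x", "y"), c("x", "z")),
    L2 = rbind(c("b", "c"), c("y", "z"))))
  dm <- degree_corrected_sample(M, in_set = c("a", "b"),
                                out_pool = c("x", "y", "z"), seed = 1)
  expect_equal(dm$mismatches, 0L)
  deg <- multidegree(M)
  expect_equal(sort(unname(deg[dm$matched])), sort(unname(deg[c("a", "b")])))
  expect_error(degree_corrected_sample(M, "a", character(0)), "empty")
  expect_error(degree_corrected_sample(M, "a", c("a", "x")), "disjoint")

  ## synthetic instance with a matchable pool: a random periphery in-set has
  ## the same degree distribution as the remaining pool, so matching brings
  ## the mean multidegree within 5%
  cfg <- test_planted_config(n_layers = 2)
  g <- generate_multiplex(cfg, seed = 42)
  peri <- setdiff(g$network$nodes, g$core)
  set.seed(8)
  in_set <- sample(peri, 60)
  pool <- setdiff(peri, in_set)
  dm2 <- degree_corrected_sample(g$network, in_set, pool, seed = 5)
  d <- multidegree(g$network)
  expect_lt(abs(mean(d[dm2$matched]) - mean(d[in_set])) / mean(d[in_set]),
            0.05)
})

test_that("group comparisons use the right statistic and recover directions", {
  fx <- reference_fixture()
  at <- fx$attributes
  same <- compare_groups(at, at$word[1:20], at$word[1:20],
                         repetitions = 50, seed = 1)
  expect_equal(same$in_value, same$out_value, tolerance = 1e-12)
  expect_equal(same$statistic[same$attribute == "log_frequency"], "mean")
  expect_equal(same$statistic[same$attribute == "polysemy"], "mean")
  expect_equal(same$statistic[same$attribute == "aoa_mean"], "median")

  ## planted core: earlier acquired, more frequent, more polysemous
  cfg <- test_planted_config(n_layers = 2)
  g <- generate_multiplex(cfg, seed = 11)
  peri <- setdiff(g$network$nodes, g$core)
  cmp <- compare_groups(g$attributes, g$core, peri, repetitions = 200,
                        seed = 2)
  get <- function(a, col) cmp[cmp$attribute == a, col]
  expect_lt(get("aoa_mean", "in_value"), get("aoa_mean", "out_value"))
  expect_gt(get("log_frequency", "in_value"), get("log_frequency", "out_value"))
  expect_gt(get("polysemy", "in_value"), get("polysemy", "out_value"))
  expect_lt(get("length", "in_value"), get("length", "out_value"))

  ## shifted distributions: median ordering recovered
  set.seed(9)
  mk <- function(words, shift) word_attributes(data.frame(
    word = words, aoa_mean = stats::rnorm(length(words), 5 + shift), aoa_sd = 1,
    frequency = 10, polysemy = 1, concreteness = 3, reaction_time = 600,
    length = 4))
  atl <- rbind(mk(sprintf("lo%03d", 1:300), 0), mk(sprintf("hi%03d", 1:300), 1))
  class(atl) <- c("word_attributes", "data.frame")
  cmp2 <- compare_groups(atl, atl$word[1:300], atl$word[301:600],
                         repetitions = 200, seed = 3,
                         attributes = "aoa_mean")
  expect_lt(cmp2$in_value, cmp2$out_value)
  expect_error(compare_groups(atl, character(0), atl$word), "non-empty")
})

test_that("sign test matches the exact binomial", {
  expect_equal(sign_test(c(1, 1, 1, 1, -1, -1, -1, -1))$p_value, 1)
  expect_equal(sign_test(rep(1, 8))$p_value, 2 * (1 / 2)^8)
  expect_error(sign_test(c(0, 0)), "zero")

  set.seed(4)
  for (i in 1:20) {
    d <- stats::rnorm(30, mean = 0.2)
    d <- d[d != 0]
    got <- sign_test(d)
    oracle <- stats::binom.test(sum(d > 0), length(d), 0.5)$p.value
    expect_equal(got$p_value, oracle)
  }
  one_sided <- sign_test(rep(1, 8), alternative = "greater")
  expect_equal(one_sided$p_value, (1 / 2)^8)
})

test_that("kendall tau is tie-corrected and agrees with pair counting", {
  expect_equal(kendall_tau(1:10, 1:10), 1)
  expect_equal(kendall_tau(1:10, 10:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")

  set.seed(6)
  for (i in 1:25) {
    x <- sample(1:8, 30, replace = TRUE)  # heavy ties
    y <- x + sample(1:5, 30, replace = TRUE)
    expect_equal(kendall_tau(x, y), tau_b_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("cumulative curves are proper CDFs with renormalised concreteness", {
  at <- word_attributes(data.frame(
    word = letters[1:10], aoa_mean = 1:10, aoa_sd = 1,
    frequency = c(1, 2, 2, 3, 5, 8, 13, 21, 34, 55), polysemy = 1,
    concreteness = seq(1, 5, length.out = 10), reaction_time = 600,
    length = 4))
  cc <- cumulative_curve(at, "frequency", thresholds = c(0, 2, 5, 100))
  expect_equal(cc$probability, c(0, 0.3, 0.5, 1))  # hand count
  expect_true(all(diff(cc$probability) >= 0))

  ## concreteness rescaled to [0, 1] before thresholding
  cc2 <- cumulative_curve(at, "concreteness", thresholds = c(0.5, 1))
  expect_equal(cc2$probability, c(0.5, 1))
  expect_error(cumulative_curve(at, "nope", thresholds = 1), "unknown")
})

test_that("core-periphery densities classify every link and rank correctly", {
  ## complete layer: all three densities are 1
  cmpl <- t(combn(letters[1:6], 2))
  M <- load_multiplex(list(L1 = cmpl))
  cp <- core_periphery_densities(M, letters[1:3])
  expect_equal(unname(unlist(cp$densities)), rep(1, 3))

  ## no boundary edges
  M2 <- load_multiplex(list(L1 = rbind(c("a", "b"), c("x", "y"))))
  cp2 <- core_periphery_densities(M2, c("a", "b"))
  expect_equal(cp2$counts$in_out, 0)
  expect_equal(cp2$densities$in_in, 1)

  expect_error(core_periphery_densities(M, M$nodes), "proper subset")
  expect_error(core_periphery_densities(M, character(0)), "proper subset")

  ## counts equal brute-force pair classification on random instances
  for (s in 1:5) {
    Mr <- random_test_multiplex(20, n_layers = 2, p = 0.2, seed = 30 + s)
    core <- sample(Mr$nodes, 7)
    cp3 <- core_periphery_densities(Mr, core)
    for (li in seq_along(Mr$layers)) {
      e <- Mr$edges[[Mr$layers[li]]]
      w1 <- Mr$nodes[e[, 1]] %in% core
      w2 <- Mr$nodes[e[, 2]] %in% core
      expect_equal(cp3$counts$in_in[li], sum(w1 & w2))
      expect_equal(cp3$counts$in_out[li], sum(xor(w1, w2)))
      expect_equal(cp3$counts$out_out[li], sum(!w1 & !w2))
      expect_equal(sum(cp3$counts[li, ]), nrow(e))
    }
  }

  ## planted construction: p_In/In > p_In/Out > p_Out/Out on every layer
  cfg <- test_planted_config(n_layers = 2)
  g <- generate_multiplex(cfg, seed = 3)
  cp4 <- core_periphery_densities(g$network, g$core)
  expect_true(all(cp4$densities$in_in > cp4$densities$in_out))
  expect_true(all(cp4$densities$in_out > cp4$densities$out_out))
  expect_equal(max(cp4$normalised), 1)
})

test_that("group comparison is invariant to word order in its inputs", {
  fx <- reference_fixture()
  at <- fx$attributes
  in_set <- at$word[1:15]; out_set <- at$word[16:60]
  c1 <- compare_groups(at, in_set, out_set, repetitions = 400, seed = 5)
  set.seed(1)
  c2 <- compare_groups(at, rev(in_set), sample(out_set), repetitions = 400,
                       seed = 5)
  ## in-group is evaluated at full size: exactly invariant; the subsampled
  ## out-group agrees within Monte Carlo standard error
  expect_equal(c1$in_value, c2$in_value, tolerance = 1e-9)
  se <- (c1$out_error + c2$out_error) / sqrt(400) + 1e-9
  expect_true(all(abs(c1$out_value - c2$out_value) < 6 * se))
})
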