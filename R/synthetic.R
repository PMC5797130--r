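#' Configuration for the synthetic planted-core multiplex generator
#'
#' Describes a synthetic multiplex lexicon: a block model with a densely
#' interlinked planted core (viable on every layer by construction), a sparse
#' periphery with heavy-tailed extra connectivity, and psycholinguistic node
#' attributes drawn from a Gaussian copula so that their Kendall rank
#' correlations with age of acquisition match configurable targets.
#'
#' The last layer acts as a connectivity bottleneck: core words are linked on
#' it almost exclusively through a small set of "connector" words, which are
#' the core words with the highest ages of acquisition. Under normative
#' (age-ordered) growth the non-connector core is therefore assembled long
#' before the first connector arrives, and that arrival makes the whole
#' assembled core viable at once — the planted analogue of an explosive
#' emergence driven by late keystone links. Under random orderings connectors
#' arrive early and the core becomes viable by gradual accretion instead.
#'
#' @param N total number of words.
#' @param n_layers number of layers (reference configuration: 4).
#' @param n_core size of the planted core.
#' @param p_core within-core edge probability per non-bottleneck layer.
#' @param p_boundary core-periphery edge probability per layer.
#' @param p_periphery periphery-periphery edge probability per layer.
#' @param layer_overlap fraction of the within-core edge budget drawn once
#'   and shared by all non-bottleneck layers; shared wiring makes the core's
#'   mutual connectivity assemble smoothly rather than in large jumps.
#' @param n_connectors number of bottleneck connector words.
#' @param bottleneck_boundary_scale multiplier on `p_boundary` for the
#'   bottleneck layer.
#' @param bottleneck_periphery_scale multiplier on `p_periphery` for the
#'   bottleneck layer; kept below `bottleneck_boundary_scale * p_boundary /
#'   p_periphery` so the core-periphery density ranking holds on the
#'   bottleneck too.
#' @param degree_exponent tail exponent of the periphery's extra-degree
#'   distribution (edge-stub augmentation).
#' @param stub_mean mean extra multidegree per periphery word from stub
#'   augmentation (spread over all layers).
#' @param core_aoa_shift downward shift, in latent standard-normal units, of
#'   the core's age-of-acquisition latent (core words are acquired earlier).
#' @param tau named Kendall-tau targets to age of acquisition for
#'   `frequency`, `multidegree`, `polysemy`, `length`, `concreteness`,
#'   `reaction_time`.
#' @param marginals named list of marginal parameters, see defaults.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(N = 2000, n_layers = 4, n_core = 200,
                             p_core = 0.08, p_boundary = 0.004,
                             p_periphery = 0.0015,
                             layer_overlap = 0.5,
                             n_connectors = 20,
                             bottleneck_boundary_scale = 0.3,
                             bottleneck_periphery_scale = 0.5,
                             degree_exponent = 2.5,
                             stub_mean = 2,
                             core_aoa_shift = 1.5,
                             tau = c(frequency = -0.47, multidegree = -0.31,
                                     polysemy = -0.26, length = 0.24,
                                     concreteness = -0.30,
                                     reaction_time = 0.30),
                             marginals = list(
                               aoa_mean = c(location = 9, scale = 3),
                               aoa_sd = c(min = 0.3, max = 1.2),
                               frequency = c(meanlog = 5, sdlog = 2),
                               polysemy = c(prob = 0.25),
                               concreteness = c(min = 1, max = 5),
                               reaction_time = c(mean = 600, sd = 60),
                               length = c(offset = 2, lambda = 4),
                               degree_weight = c(xmin = 1))) {
  cfg <- list(N = N, n_layers = n_layers, n_core = n_core, p_core = p_core,
              p_boundary = p_boundary, p_periphery = p_periphery,
              layer_overlap = layer_overlap, n_connectors = n_connectors,
              bottleneck_boundary_scale = bottleneck_boundary_scale,
              bottleneck_periphery_scale = bottleneck_periphery_scale,
              degree_exponent = degree_exponent, stub_mean = stub_mean,
              core_aoa_shift = core_aoa_shift, tau = tau,
              marginals = marginals)
  bad <- character(0)
  if (!(n_core >= 3 && n_core < N)) bad <- c(bad, "n_core")
  if (n_layers < 1) bad <- c(bad, "n_layers")
  probs <- c(p_core = p_core, p_boundary = p_boundary,
             p_periphery = p_periphery, layer_overlap = layer_overlap)
  bad <- c(bad, names(probs)[probs < 0 | probs > 1])
  if (!(p_core > p_boundary && p_boundary > p_periphery))
    bad <- c(bad, "p_core > p_boundary > p_periphery")
  if (n_connectors < 1 || n_connectors >= n_core) bad <- c(bad, "n_connectors")
  if (p_boundary * bottleneck_boundary_scale <=
      p_periphery * bottleneck_periphery_scale)
    bad <- c(bad, "bottleneck boundary must stay denser than its periphery")
  if (degree_exponent <= 1) bad <- c(bad, "degree_exponent")
  if (any(abs(tau) >= 1)) bad <- c(bad, "tau")
  if (length(bad))
    stop(sprintf("invalid synthetic configuration field(s): %s",
                 paste(unique(bad), collapse = ", ")))
  structure(cfg, class = "synthetic_config")
}

layer_names_for <- function(n_layers) {
  base <- c("free_association", "synonymy", "taxonomic", "phonological")
  if (n_layers <= length(base)) return(base[seq_len(n_layers)])
  c(base, paste0("layer", seq_len(n_layers - length(base))))
}

#' Copula-correlated psycholinguistic attributes
#'
#' Draws word attributes from a Gaussian copula: a latent standard-normal
#' age-of-acquisition score, and per attribute a latent with correlation
#' `rho = sin(pi * tau / 2)` to it (Greiner's relation, so that the latent
#' pair has Kendall tau equal to the target). Marginals are applied by
#' inverse-CDF transform: log-normal frequency, shifted-geometric polysemy,
#' normal AoA mean and reaction time, uniform concreteness, shifted-Poisson
#' length, Pareto connectivity weight (`degree_weight`, the target for the
#' generator's heavy-tailed multidegree). Core words (positive coreness) have
#' their AoA latent shifted downwards before the attribute latents are drawn,
#' so all attribute contrasts of the core follow from the single shift.
#'
#' @param config a [synthetic_config()].
#' @param coreness numeric vector (one score per word, typically 0/1); scaled
#'   by `config$core_aoa_shift`.
#' @param seed integer seed.
#' @param words optional word names (default `w0001`, ...).
#' @return a [word_attributes()] table with an extra `degree_weight` column.
#' @export
copula_correlated_attributes <- function(config, coreness, seed = NULL,
                                         words = NULL) {
  n <- length(coreness)
  if (is.null(words))
    words <- sprintf(paste0("w%0", max(4, nchar(n)), "d"), seq_len(n))
  mg <- config$marginals
  tau <- config$tau
  with_seed(seed, {
    z0 <- stats::rnorm(n) - config$core_aoa_shift * coreness
    latent <- function(tau_target) {
      rho <- sin(pi * tau_target / 2)
      rho * z0 + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    u <- function(z) stats::pnorm(z)
    aoa_mean <- mg$aoa_mean[["location"]] + mg$aoa_mean[["scale"]] * z0
    frequency <- round(stats::qlnorm(u(latent(tau[["frequency"]])),
                                     mg$frequency[["meanlog"]],
                                     mg$frequency[["sdlog"]]))
    polysemy <- 1 + stats::qgeom(u(latent(tau[["polysemy"]])),
                                 mg$polysemy[["prob"]])
    concreteness <- stats::qunif(u(latent(tau[["concreteness"]])),
                                 mg$concreteness[["min"]],
                                 mg$concreteness[["max"]])
    reaction_time <- stats::qnorm(u(latent(tau[["reaction_time"]])),
                                  mg$reaction_time[["mean"]],
                                  mg$reaction_time[["sd"]])
    length_ <- mg$length[["offset"]] +
      stats::qpois(u(latent(tau[["length"]])), mg$length[["lambda"]])
    ## Pareto with tail exponent gamma: survival (x/xmin)^-(gamma - 1)
    shape <- config$degree_exponent - 1
    degree_weight <- mg$degree_weight[["xmin"]] *
      (1 - u(latent(tau[["multidegree"]])))^(-1 / shape)
    aoa_sd <- stats::runif(n, mg$aoa_sd[["min"]], mg$aoa_sd[["max"]])
    df <- data.frame(word = words, aoa_mean = aoa_mean, aoa_sd = aoa_sd,
                     frequency = frequency, polysemy = polysemy,
                     concreteness = concreteness,
                     reaction_time = reaction_time, length = length_,
                     degree_weight = degree_weight,
                     stringsAsFactors = FALSE)
    word_attributes(df)
  })
}

## ---- random pair sampling helpers -------------------------------------

## sample Bernoulli(p) edges among unordered pairs of 'idx'
sample_within <- function(idx, p) {
  n <- length(idx)
  np <- n * (n - 1) / 2
  if (np < 1 || p <= 0) return(cbind(integer(0), integer(0)))
  m <- stats::rbinom(1, np, p)
  if (m == 0) return(cbind(integer(0), integer(0)))
  t <- sample(np, m)
  ij <- unrank_pairs(t, n)
  cbind(idx[ij[, 1]], idx[ij[, 2]])
}

## sample Bernoulli(p) edges between 'idx_a' and 'idx_b' (disjoint)
sample_between <- function(idx_a, idx_b, p) {
  np <- as.numeric(length(idx_a)) * length(idx_b)
  if (np < 1 || p <= 0) return(cbind(integer(0), integer(0)))
  m <- stats::rbinom(1, np, p)
  if (m == 0) return(cbind(integer(0), integer(0)))
  t <- sample(np, m) - 1
  a <- (t %/% length(idx_b)) + 1
  b <- (t %% length(idx_b)) + 1
  cbind(idx_a[a], idx_b[b])
}

## unrank linear indices of unordered pairs (i < j) of 1..n, i-major order
unrank_pairs <- function(t, n) {
  ## pairs with first element i occupy ranks (S(i-1), S(i)], where
  ## S(i) = i*n - i*(i+1)/2
  i <- floor(n + 0.5 - sqrt((n - 0.5)^2 - 2 * (t - 1)))
  S_prev <- (i - 1) * n - i * (i - 1) / 2
  ## fix up floating point at block boundaries
  too_big <- S_prev >= t
  while (any(too_big)) {
    i[too_big] <- i[too_big] - 1
    S_prev <- (i - 1) * n - i * (i - 1) / 2
    too_big <- S_prev >= t
  }
  S_cur <- i * n - i * (i + 1) / 2
  too_small <- t > S_cur
  while (any(too_small)) {
    i[too_small] <- i[too_small] + 1
    S_prev <- (i - 1) * n - i * (i - 1) / 2
    S_cur <- i * n - i * (i + 1) / 2
    too_small <- t > S_cur
  }
  j <- i + (t - S_prev)
  cbind(as.integer(i), as.integer(j))
}

## ---- generator ---------------------------------------------------------

#' Generate a synthetic planted-core multiplex lexicon
#'
#' Builds a multiplex network plus matching attributes according to a
#' [synthetic_config()]: Bernoulli block edges (dense within the planted
#' core, sparse across the boundary and in the periphery), partially shared
#' core wiring across the non-bottleneck layers, a bottleneck layer on which
#' the core is tied together by late-acquired connector words, heavy-tailed
#' periphery stub augmentation driven by the copula's `degree_weight`, and a
#' repair step guaranteeing every word at least one edge on at least one
#' layer. Attribute bundles are assigned to nodes by matching the
#' `degree_weight` rank to the realised multidegree rank (within the
#' non-connector core and within the periphery separately), so that the
#' realised multidegree inherits the configured rank correlation with age of
#' acquisition.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the same seed reproduces the instance exactly.
#' @return list with elements `network` (a `multiplex`), `attributes` (a
#'   [word_attributes()] table with `degree_weight`), `core` (character),
#'   `connectors` (character) and `config`.
#' @export
generate_multiplex <- function(config, seed = NULL) {
  if (!inherits(config, "synthetic_config"))
    stop("'config' must be a synthetic_config object")
  N <- config$N
  words <- sprintf(paste0("w%0", max(4, nchar(N)), "d"), seq_len(N))
  core_idx <- seq_len(config$n_core)
  peri_idx <- setdiff(seq_len(N), core_idx)
  lnames <- layer_names_for(config$n_layers)
  bottleneck <- lnames[config$n_layers]

  seeds <- derive_seeds(seed, 3L)
  attrs <- copula_correlated_attributes(
    config, coreness = as.numeric(seq_len(N) %in% core_idx),
    seed = seeds[1], words = words)

  ## connectors: core words with the highest mean age of acquisition
  core_aoa <- attrs$aoa_mean[core_idx]
  conn_idx <- core_idx[order(-core_aoa)][seq_len(config$n_connectors)]
  plain_core <- setdiff(core_idx, conn_idx)

  edges <- with_seed(seeds[2], {
    ## shared core wiring for all non-bottleneck layers
    shared <- sample_within(core_idx, config$p_core * config$layer_overlap)
    w_peri <- attrs$degree_weight[peri_idx]
    stub_m_per_layer <- round(config$stub_mean * length(peri_idx) /
                                (2 * config$n_layers))
    lapply(stats::setNames(lnames, lnames), function(ln) {
      parts <- list()
      if (ln != bottleneck || config$n_layers == 1L) {
        parts$core <- rbind(shared,
                            sample_within(core_idx,
                                          config$p_core *
                                            (1 - config$layer_overlap)))
        parts$boundary <- sample_between(core_idx, peri_idx,
                                         config$p_boundary)
        parts$periphery <- sample_within(peri_idx, config$p_periphery)
      } else {
        ## bottleneck: core held together by connector words only
        conn_pairs <- expand.grid(conn_idx, core_idx)
        conn_pairs <- conn_pairs[conn_pairs[, 1] != conn_pairs[, 2], ]
        parts$core <- as.matrix(conn_pairs)
        parts$boundary <- sample_between(
          core_idx, peri_idx,
          config$p_boundary * config$bottleneck_boundary_scale)
        parts$periphery <- sample_within(
          peri_idx, config$p_periphery * config$bottleneck_periphery_scale)
      }
      if (stub_m_per_layer > 0 && length(peri_idx) > 1) {
        a <- sample(peri_idx, stub_m_per_layer, replace = TRUE, prob = w_peri)
        b <- sample(peri_idx, stub_m_per_layer, replace = TRUE, prob = w_peri)
        keep <- a != b
        parts$stubs <- cbind(a[keep], b[keep])
      }
      e <- do.call(rbind, parts)
      canonical_edges(e[, 1], e[, 2])
    })
  })

  ## repair: every word needs at least one edge on at least one layer
  deg <- integer(N)
  for (e in edges) deg <- deg + tabulate(e[, 1], N) + tabulate(e[, 2], N)
  iso <- which(deg == 0L)
  if (length(iso)) {
    repair <- with_seed(seeds[3], {
      lapply(iso, function(v)
        list(layer = sample(lnames, 1),
             partner = sample(setdiff(seq_len(N), v), 1)))
    })
    for (k in seq_along(iso)) {
      r <- repair[[k]]
      e <- edges[[r$layer]]
      edges[[r$layer]] <- canonical_edges(c(e[, 1], iso[k]),
                                          c(e[, 2], r$partner))
    }
  }

  M <- structure(list(nodes = words, layers = lnames, edges = edges),
                 class = "multiplex")

  ## rank-match attribute bundles to realised multidegree
  realised <- unname(multidegree(M))
  attrs <- rank_match_attributes(attrs, realised, plain_core, peri_idx)

  list(network = M, attributes = attrs,
       core = words[core_idx], connectors = words[conn_idx],
       config = config)
}

## permute attribute bundles within each group so that degree_weight rank
## matches realised multidegree rank (word column stays with the node)
rank_match_attributes <- function(attrs, realised_deg, ...) {
  groups <- list(...)
  value_cols <- setdiff(names(attrs), "word")
  for (g in groups) {
    if (length(g) < 2) next
    node_order <- g[order(realised_deg[g])]
    bundle_order <- g[order(attrs$degree_weight[g])]
    attrs[node_order, value_cols] <- attrs[bundle_order, value_cols]
  }
  attrs
}

#' Deterministic 60-word reference fixture
#'
#' A small hand-constructed two-layer multiplex whose viable-cluster
#' structure is fully known: a 10-word planted core (`w01`-`w10`) wired as
#' two different cycles plus chords, which is the unique maximal non-trivial
#' viable cluster, and a 50-word periphery forming a chain on the first layer
#' and two interleaved chains on the second, attached to the core on the
#' second layer only — so no viable cluster can ever reach outside the core.
#' Under the built-in age-of-acquisition ordering (`w01`, `w02`, ...) the
#' core's LVC appears at step 9 with a jump of 9 words and is complete at
#' step 10.
#'
#' @return list with `network`, `attributes`, `lvc_members` (the planted
#'   core) and `expected_lvc_sizes` (the growth trajectory under the mean-AoA
#'   ordering).
#' @export
reference_fixture <- function() {
  idx2 <- function(i) sprintf("w%02d", i)
  core_A <- rbind(cbind(1:9, 2:10), c(10, 1),
                  c(1, 4), c(2, 6), c(3, 8), c(5, 9), c(7, 10))
  odd_cycle <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  core_B <- cbind(odd_cycle, c(odd_cycle[-1], 1))
  chain_A <- cbind(11:59, 12:60)
  odd_B <- cbind(seq(11, 57, 2), seq(13, 59, 2))
  even_B <- cbind(seq(12, 58, 2), seq(14, 60, 2))
  attach_B <- rbind(c(1, 11), c(2, 12))
  eA <- rbind(core_A, chain_A)
  eB <- rbind(core_B, odd_B, even_B, attach_B)
  M <- multiplex(list(semantic = cbind(idx2(eA[, 1]), idx2(eA[, 2])),
                      phonological = cbind(idx2(eB[, 1]), idx2(eB[, 2]))),
                 drop_isolated = FALSE)
  i <- 1:60
  attrs <- word_attributes(data.frame(
    word = idx2(i),
    aoa_mean = ifelse(i <= 10, 2 + 0.15 * (i - 1), 4 + 0.08 * (i - 11)),
    aoa_sd = 0.2 + 0.01 * i,
    frequency = round(5000 / i),
    polysemy = 1 + (60 - i) %/% 6,
    concreteness = 1 + 4 * (60 - i) / 59,
    reaction_time = 500 + 3 * i,
    length = 3 + i %/% 12,
    stringsAsFactors = FALSE))
  list(network = M, attributes = attrs,
       lvc_members = idx2(1:10),
       expected_lvc_sizes = c(rep(0L, 8), 9L, rep(10L, 51)))
}
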