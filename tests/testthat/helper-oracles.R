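# Independent oracles and small random-instance builders used across tests.
# These deliberately avoid the package's own graph machinery: components via
# union-find, distances via igraph's distance matrix, tau via explicit pair
# counting.

# random multiplex on n named nodes: each layer an independent G(n, p);
# ensures every node has at least one edge somewhere (so the constructor
# does not drop nodes and sizes stay predictable)
random_test_multiplex <- function(n, n_layers = 2, p = 0.3, seed = 1,
                                  correlated = FALSE) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(n, 2))
  base_keep <- stats::runif(nrow(pairs)) < p
  layers <- lapply(seq_len(n_layers), function(l) {
    keep <- if (correlated) {
      ## share half of the wiring across layers
      base_keep | (stats::runif(nrow(pairs)) < p / 2)
    } else {
      stats::runif(nrow(pairs)) < p
    }
    m <- cbind(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]])
    if (!nrow(m)) m <- cbind(nodes[1], nodes[2])  # no empty layers
    m
  })
  names(layers) <- paste0("L", seq_len(n_layers))
  multiplex(layers, nodes = nodes, drop_isolated = FALSE)
}

# union-find connected components of one layer (edge matrix of node indices)
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, 0L)
}

# tie-corrected Kendall tau-b by explicit O(n^2) concordant/discordant counts
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# hand-built ordering without going through a scheme constructor
new_ordering_for_test <- function(words)
  structure(list(sequence = words, scheme = "random", seed = NULL),
            class = "acquisition_ordering")

# membership sets of a cluster list, for order-insensitive comparison
cluster_sets <- function(clusters) lapply(clusters, function(cl) cl$members)

# small planted-core configuration used by null-model and statistics tests:
# two correlated layers, a dense 40-word core, light periphery so that
# viability hinges on the inter-layer alignment of the core
test_planted_config <- function(n_layers = 2) {
  synthetic_config(N = 400, n_layers = n_layers, n_core = 40, p_core = 0.25,
                   p_boundary = 0.01, p_periphery = 0.002,
                   n_connectors = 4, stub_mean = 0.5)
}
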