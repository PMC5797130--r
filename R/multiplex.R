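#' Multiplex lexical networks
#'
#' A `multiplex` object represents a node-aligned multilayer network: a single
#' shared set of words replicated across named layers, each layer holding one
#' undirected, unweighted edge type (e.g. free associations, synonyms,
#' taxonomic relations, phonological similarities).
#'
#' Internally the object stores the node vocabulary as a character vector in
#' lexicographic order and, per layer, a canonical two-column integer matrix of
#' edges (indices into the node vector, first column < second column, rows
#' sorted). This canonical form makes file round-trips and equality checks
#' deterministic.
#'
#' @param edges named list, one element per layer, each a two-column matrix or
#'   data frame of word pairs (character) or node indices (integer).
#' @param nodes optional character vector of node names. If omitted, the union
#'   of all endpoint names is used. Required when `edges` are given as indices.
#' @param drop_isolated drop nodes with degree zero on every layer (the rule
#'   for full lexicons: every word must be connected somewhere). Induced
#'   subnetworks relax this, see [induced_subnetwork()].
#'
#' @return An object of class `multiplex` with elements `nodes` (character),
#'   `layers` (character) and `edges` (named list of integer matrices).
#' @export
multiplex <- function(edges, nodes = NULL, drop_isolated = TRUE) {
  if (!is.list(edges) || length(edges) == 0L)
    stop("'edges' must be a non-empty named list of per-layer edge tables")
  layer_names <- names(edges)
  if (is.null(layer_names) || anyDuplicated(layer_names) || any(layer_names == ""))
    stop("layer names must be unique and non-empty")

  as_char_pairs <- function(tab, layer) {
    if (is.data.frame(tab)) tab <- as.matrix(tab[, 1:2])
    if (is.null(tab) || length(tab) == 0L)
      return(matrix(character(0), ncol = 2))
    if (!is.matrix(tab) || ncol(tab) < 2L)
      stop(sprintf("layer '%s': edge table must have two columns", layer))
    matrix(as.character(tab[, 1:2]), ncol = 2)
  }
  pair_tabs <- Map(as_char_pairs, edges, layer_names)

  if (is.null(nodes)) {
    nodes <- unique(unlist(lapply(pair_tabs, as.vector), use.names = FALSE))
  } else {
    nodes <- as.character(nodes)
  }
  nodes <- sort(unique(nodes), method = "radix")

  canon <- lapply(layer_names, function(ln) {
    tab <- pair_tabs[[ln]]
    i <- match(tab[, 1], nodes)
    j <- match(tab[, 2], nodes)
    if (anyNA(i) || anyNA(j))
      stop(sprintf("layer '%s': edge endpoint not in node set", ln))
    loops <- i == j
    if (any(loops)) {
      warning(sprintf("layer '%s': %d self-loop row(s) rejected", ln, sum(loops)))
      i <- i[!loops]; j <- j[!loops]
    }
    canonical_edges(i, j)
  })
  names(canon) <- layer_names

  if (any(vapply(canon, nrow, 0L) == 0L)) {
    bad <- layer_names[vapply(canon, nrow, 0L) == 0L]
    stop(sprintf("empty layer(s) after cleaning: %s", paste(bad, collapse = ", ")))
  }

  M <- structure(list(nodes = nodes, layers = layer_names, edges = canon),
                 class = "multiplex")
  if (drop_isolated) {
    deg <- multidegree(M)
    if (any(deg == 0L)) {
      iso <- M$nodes[deg == 0L]
      warning(sprintf("dropping %d node(s) isolated on all layers", length(iso)))
      M <- induced_subnetwork(M, setdiff(M$nodes, iso))
    }
  }
  M
}

## canonical undirected storage: i < j, rows sorted, duplicates removed
canonical_edges <- function(i, j) {
  if (length(i) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  lo <- pmin(i, j); hi <- pmax(i, j)
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]
  dup <- duplicated(cbind(lo, hi))
  cbind(i = lo[!dup], j = hi[!dup])
}

#' @export
print.multiplex <- function(x, ...) {
  cat(sprintf("multiplex network: %d nodes, %d layers\n",
              length(x$nodes), length(x$layers)))
  for (ln in x$layers)
    cat(sprintf("  %s: %d edges\n", ln, nrow(x$edges[[ln]])))
  invisible(x)
}

#' Number of nodes of a multiplex network
#' @param M a `multiplex` object.
#' @return integer count of words in the shared node set.
#' @export
n_nodes <- function(M) length(M$nodes)

#' Load a multiplex network from per-layer edge tables
#'
#' Accepts either a named list of two-column tables (one per layer) or paths
#' to TSV files. A single three-column file (`word1 word2 layer`) can be read
#' with [read_multiplex()]. Self-loop rows are rejected with a warning,
#' reversed duplicates collapse to a single undirected edge, and words left
#' isolated on all layers are dropped with a warning.
#'
#' @param edge_tables named list mapping layer name to a two-column table of
#'   word pairs.
#' @return a [multiplex()] object.
#' @export
load_multiplex <- function(edge_tables) {
  multiplex(edge_tables, drop_isolated = TRUE)
}

#' Read a multiplex network from TSV files
#'
#' Two on-disk conventions are supported: one two-column TSV per layer
#' (`word1<TAB>word2`), or a single three-column TSV (`word1 word2 layer`).
#' Lines starting with `#` are ignored; files are read as UTF-8.
#'
#' @param paths named character vector of file paths (names = layer names),
#'   or a single unnamed path to a three-column file.
#' @return a [multiplex()] object.
#' @export
read_multiplex <- function(paths) {
  read_tab <- function(p)
    utils::read.table(p, sep = "\t", header = FALSE, comment.char = "#",
                      quote = "", stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8", colClasses = "character")
  if (length(paths) == 1L && is.null(names(paths))) {
    tab <- read_tab(paths)
    if (ncol(tab) < 3L) stop("single-file format requires three columns: word1, word2, layer")
    split_tabs <- split(tab[, 1:2], tab[, 3])
    return(load_multiplex(split_tabs))
  }
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("per-layer files must be named by layer")
  load_multiplex(lapply(paths, read_tab))
}

#' Write a multiplex network to canonical TSV files
#'
#' Writes one two-column TSV per layer in canonical order (endpoints sorted
#' within a row, rows sorted lexicographically), so that
#' `read_multiplex(write_multiplex(M, dir))` reproduces the files
#' byte-identically.
#'
#' @param M a `multiplex` object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; files are named `<prefix><layer>.tsv`.
#' @return invisibly, the named vector of file paths written.
#' @export
write_multiplex <- function(M, dir, prefix = "layer_") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(M$layers, function(ln)
    file.path(dir, paste0(prefix, ln, ".tsv")), "")
  for (ln in M$layers) {
    e <- M$edges[[ln]]
    tab <- cbind(M$nodes[e[, 1]], M$nodes[e[, 2]])
    utils::write.table(tab, paths[[ln]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(paths)
}

#' Induced multiplex subnetwork
#'
#' Restricts the network to a node subset, keeping only edges with both
#' endpoints inside the subset. Unlike [load_multiplex()], nodes isolated on
#' all layers are retained: growth prefixes legitimately contain words whose
#' connections have not yet been acquired.
#'
#' @param M a `multiplex` object.
#' @param S character vector of node names, a subset of `M$nodes`.
#' @return a `multiplex` object on the node set `S` (possibly with empty
#'   layers and isolated nodes).
#' @export
induced_subnetwork <- function(M, S) {
  S <- as.character(S)
  idx <- match(S, M$nodes)
  if (anyNA(idx))
    stop(sprintf("unknown node(s): %s",
                 paste(utils::head(S[is.na(idx)], 5), collapse = ", ")))
  keep <- logical(length(M$nodes))
  keep[idx] <- TRUE
  nodes <- M$nodes[keep]          # preserves lexicographic order
  remap <- integer(length(M$nodes))
  remap[keep] <- seq_along(nodes)
  edges <- lapply(M$edges, function(e) {
    inS <- keep[e[, 1]] & keep[e[, 2]]
    canonical_edges(remap[e[inS, 1]], remap[e[inS, 2]])
  })
  structure(list(nodes = nodes, layers = M$layers, edges = edges),
            class = "multiplex")
}

## per-layer adjacency lists (list over layers of list over nodes of integer
## neighbour vectors); the workhorse representation for BFS-based routines
multiplex_adjacency <- function(M) {
  n <- length(M$nodes)
  lapply(M$edges, function(e) {
    adj <- vector("list", n)
    if (nrow(e)) {
      ends <- c(e[, 1], e[, 2])
      nbrs <- c(e[, 2], e[, 1])
      o <- order(ends)
      adj_split <- split(nbrs[o], factor(ends[o], levels = seq_len(n)))
      adj <- unname(adj_split)
    } else {
      adj <- rep(list(integer(0)), n)
    }
    adj
  })
}

## BFS from node v over one layer's adjacency, restricted to TRUE cells of
## 'mask'; returns the logical membership vector of the component of v
bfs_component <- function(v, adj, mask) {
  n <- length(mask)
  vis <- logical(n)
  if (!mask[v]) return(vis)
  vis[v] <- TRUE
  queue <- v
  while (length(queue)) {
    nbrs <- unlist(adj[queue], use.names = FALSE)
    queue <- unique(nbrs[mask[nbrs] & !vis[nbrs]])
    vis[queue] <- TRUE
  }
  vis
}

#' Connected components of one layer
#'
#' Partition of the full node set into connected components of a single
#' layer's graph; nodes without edges on that layer form singleton components.
#'
#' @param M a `multiplex` object.
#' @param layer layer name.
#' @return list of character vectors (the components), largest first.
#' @export
layer_components <- function(M, layer) {
  if (!layer %in% M$layers) stop(sprintf("unknown layer '%s'", layer))
  g <- layer_graph(M, layer)
  cmp <- igraph::components(g)
  comps <- split(M$nodes, cmp$membership)
  comps <- comps[order(-vapply(comps, length, 0L))]
  unname(comps)
}

#' Multidegree of words
#'
#' The multidegree of a word is the sum over layers of its within-layer
#' degree, i.e. the count of incident edge records across the whole multiplex.
#'
#' @param M a `multiplex` object.
#' @param words character vector of words, or `NULL` for all nodes.
#' @return named integer vector of multidegrees.
#' @export
multidegree <- function(M, words = NULL) {
  n <- length(M$nodes)
  deg <- integer(n)
  for (e in M$edges) {
    t1 <- tabulate(e[, 1], nbins = n)
    t2 <- tabulate(e[, 2], nbins = n)
    deg <- deg + t1 + t2
  }
  names(deg) <- M$nodes
  if (is.null(words)) return(deg)
  idx <- match(as.character(words), M$nodes)
  if (anyNA(idx))
    stop(sprintf("unknown word(s): %s",
                 paste(words[is.na(idx)], collapse = ", ")))
  deg[idx]
}

#' Single-layer igraph view of one layer
#' @param M a `multiplex` object.
#' @param layer layer name.
#' @return an igraph graph on all nodes of `M`.
#' @export
layer_graph <- function(M, layer) {
  if (!layer %in% M$layers) stop(sprintf("unknown layer '%s'", layer))
  graph_from_canonical(M$edges[[layer]], length(M$nodes))
}

graph_from_canonical <- function(e, n) {
  if (nrow(e) == 0L) return(igraph::make_empty_graph(n, directed = FALSE))
  pad_vertices(igraph::graph_from_edgelist(e, directed = FALSE), n)
}

pad_vertices <- function(g, n) {
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Aggregate (layer-union) graph
#'
#' Union of all layers' edge sets on the shared node set; an edge present on
#' several layers collapses to a single aggregate edge. Shortest paths that
#' may traverse links on any layer reduce to paths on this graph, since
#' switching layers at a node carries no cost in a node-aligned multiplex.
#'
#' @param M a `multiplex` object.
#' @return an igraph graph with vertex names equal to `M$nodes`.
#' @export
aggregate_graph <- function(M) {
  all_e <- do.call(rbind, M$edges)
  e <- canonical_edges(all_e[, 1], all_e[, 2])
  g <- graph_from_canonical(e, length(M$nodes))
  igraph::V(g)$name <- M$nodes
  g
}

#' Word attribute table
#'
#' Validates a per-word psycholinguistic record: age-of-acquisition mean and
#' standard deviation (years), occurrence frequency, polysemy score (count of
#' definitions), concreteness rating (1-5), lexical-decision reaction time
#' (ms) and orthographic length (letters). Missing values are `NA`.
#'
#' @param df data frame with columns `word`, `aoa_mean`, `aoa_sd`,
#'   `frequency`, `polysemy`, `concreteness`, `reaction_time`, `length`.
#' @return the validated data frame, class `word_attributes`/`data.frame`,
#'   one row per word, `word` unique.
#' @export
word_attributes <- function(df) {
  req <- c("word", "aoa_mean", "aoa_sd", "frequency", "polysemy",
           "concreteness", "reaction_time", "length")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("missing attribute column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  extra <- setdiff(names(df), req)
  df <- as.data.frame(df)[, c(req, extra)]
  df$word <- as.character(df$word)
  if (anyDuplicated(df$word)) stop("duplicate words in attribute table")
  chk <- function(cond, msg) if (any(cond, na.rm = TRUE)) stop(msg)
  chk(df$aoa_sd < 0, "aoa_sd must be >= 0")
  chk(df$frequency < 0, "frequency must be >= 0")
  chk(df$polysemy < 1, "polysemy must be >= 1")
  chk(df$length < 1, "length must be >= 1")
  chk(df$concreteness < 1 | df$concreteness > 5, "concreteness must lie in [1, 5]")
  class(df) <- c("word_attributes", "data.frame")
  df
}

#' Read a word attribute table from TSV/CSV
#' @param path file path; tab- or comma-separated with a header row; empty
#'   cells are treated as missing.
#' @return a [word_attributes()] data frame.
#' @export
read_attributes <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          na.strings = c("", "NA"))
  word_attributes(df)
}

#' Write a word attribute table to TSV
#' @param attrs a [word_attributes()] data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_attributes <- function(attrs, path) {
  utils::write.table(attrs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
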