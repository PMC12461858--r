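#' Build an undirected gene network
#'
#' Internal constructor used by all readers: canonicalizes edges (unordered
#' pairs stored with the lexicographically smaller gene first), merges
#' reciprocal duplicates, drops self-loops, and keeps a sorted vertex set so
#' identical networks compare equal regardless of input order.
#'
#' @param nodes character vector of gene symbols (isolated nodes allowed).
#' @param edges tibble/data.frame with columns `from`, `to` and optionally
#'   `weight`.
#' @return An undirected `igraph` graph with vertex `name` attributes and an
#'   edge `weight` attribute when weights are supplied.
#' @keywords internal
make_network <- function(nodes, edges) {
  nodes <- sort(unique(normalize_symbols(nodes)))
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    edges$from <- normalize_symbols(edges$from)
    edges$to <- normalize_symbols(edges$to)
    loops <- edges$from == edges$to
    if (any(loops)) {
      dnb_log("dropped %d self-loop(s)", sum(loops))
      edges <- edges[!loops, , drop = FALSE]
    }
    can <- canonical_edges(edges$from, edges$to)
    edges$from <- can$from; edges$to <- can$to
    edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(missing) > 0) {
      abort(paste0("edge references undeclared node(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g
}

#' Edge table of a network
#'
#' @param g an igraph network.
#' @return Tibble with `from`, `to` (canonical order) and `weight` (NA when
#'   the graph is unweighted), sorted by edge.
#' @export
network_edges <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(tibble(from = character(), to = character(), weight = double()))
  }
  el <- igraph::as_edgelist(g)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight
  } else {
    rep(NA_real_, nrow(el))
  }
  can <- canonical_edges(el[, 1], el[, 2])
  out <- tibble(from = can$from, to = can$to, weight = w)
  out[order(out$from, out$to), ]
}

#' Read a prior interaction network from an edge list
#'
#' Accepts 2- or 3-column whitespace/tab-delimited files
#' (`geneA geneB [weight]`) and, for files ending in `.sif`, the SIF layout
#' (`geneA relation geneB`). Reciprocal duplicates are merged, self-loops are
#' dropped with a logged count, and the result is an undirected graph.
#'
#' @param path input file.
#' @return An undirected igraph network.
#' @export
read_edge_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty edge list")
  first <- tolower(strsplit(trimws(lines[1]), "[\t ]+")[[1]])
  if (identical(first[1:2], c("from", "to"))) lines <- lines[-1]  # header row
  if (length(lines) == 0) abort("edge list has a header but no edges")
  parts <- strsplit(trimws(lines), "[\t ]+")
  sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  n_ok <- if (sif) 3L else c(2L, 3L)
  from <- character(length(parts)); to <- character(length(parts))
  weight <- rep(NA_real_, length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (!(length(p) %in% n_ok)) {
      abort(sprintf("malformed line %d in '%s': expected %s fields, got %d",
                    i, path, paste(n_ok, collapse = " or "), length(p)))
    }
    if (sif) {
      from[i] <- p[1]; to[i] <- p[3]
    } else {
      from[i] <- p[1]; to[i] <- p[2]
      if (length(p) == 3) {
        w <- suppressWarnings(as.numeric(p[3]))
        if (is.na(w)) abort(sprintf("malformed weight at line %d in '%s'", i, path))
        weight[i] <- w
      }
    }
  }
  edges <- tibble(from = from, to = to, weight = weight)
  if (all(is.na(edges$weight))) edges$weight <- NULL
  make_network(c(from, to), edges)
}

#' Write a network as a TSV edge list
#'
#' @param g igraph network.
#' @param path output path.
#' @param nodes_path optional path to also write the full node list (one
#'   symbol per line), preserving isolated nodes across a round-trip.
#' @return Invisibly, `g`.
#' @export
write_edge_list <- function(g, path, nodes_path = NULL) {
  edges <- network_edges(g)
  if (all(is.na(edges$weight))) edges$weight <- NULL
  readr::write_tsv(edges, path, progress = FALSE)
  if (!is.null(nodes_path)) {
    readr::write_lines(sort(igraph::V(g)$name), nodes_path)
  }
  invisible(g)
}

#' Read a gene set
#'
#' Plain one-symbol-per-line text, or GMT (first field set name, second
#' description, rest genes; only the first record is read unless `set_name`
#' selects another).
#'
#' @param path input file.
#' @param set_name for GMT files, the record to read (default: first).
#' @return Character vector of uppercase gene symbols.
#' @export
read_gene_set <- function(path, set_name = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty gene set file")
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    recs <- strsplit(lines, "\t")
    nm <- vapply(recs, `[`, character(1), 1)
    idx <- if (is.null(set_name)) 1L else match(set_name, nm)
    if (is.na(idx)) abort(sprintf("gene set '%s' not found in %s", set_name, path))
    genes <- recs[[idx]][-(1:2)]
  } else {
    genes <- trimws(lines)
  }
  genes <- unique(normalize_symbols(genes))
  if (length(genes) == 0) abort("gene set is empty")
  genes
}
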