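options(dnbtrace.verbose = FALSE)

# small undirected weighted graph from an edge table
toy_graph <- function(from, to, weight = NULL, nodes = NULL) {
  edges <- data.frame(from = from, to = to)
  if (!is.null(weight)) edges$weight <- weight
  nodes <- nodes %||% unique(c(from, to))
  dnbtrace:::make_network(nodes, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal staged expression matrix: values is genes x samples
toy_expr <- function(values, stages, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("G%02d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, stats::setNames(as.integer(stages), samples))
}

# seeded Erdos-Renyi-ish graph over letter-named nodes
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  dnbtrace:::make_network(nodes, data.frame(from = pairs[keep, 1],
                                            to = pairs[keep, 2]))
}

# exhaustive minimum dominating set size via bitmask closed neighborhoods
brute_min_dominating_size <- function(graph) {
  nodes <- sort(igraph::V(graph)$name)
  n <- length(nodes)
  g <- igraph::permute(graph, match(igraph::V(graph)$name, nodes))
  closed <- lapply(seq_len(n), function(i) {
    unique(c(i, as.integer(igraph::neighbors(g, i))))
  })
  masks <- vapply(closed, function(idx) sum(bitwShiftL(1L, idx - 1L)), integer(1))
  full <- bitwShiftL(1L, n) - 1L
  for (k in seq_len(n)) {
    sets <- utils::combn(n, k)
    for (j in seq_len(ncol(sets))) {
      acc <- 0L
      for (i in sets[, j]) acc <- bitwOr(acc, masks[i])
      if (acc == full) return(k)
    }
  }
  n
}

# tiny config for fast end-to-end pipeline tests
mini_config <- function(seed = 1L) {
  cfg <- benchmark_config(seed = seed, n_samples_per_stage = 12L)
  cfg$simulate <- list(n_genes = 60L, n_stages = 3L, n_samples_per_stage = 12L,
                       module_size = 6L, t_star = 2L, rho_in = 0.7,
                       rho_bg = 0.55, delta = 0.8, prior_extra_edges = 30L,
                       mean_shift_per_stage = 0.5)
  cfg$gcn$d <- 8L
  cfg$gcn$epochs <- 10L
  cfg$scoring$k_max <- 6L
  cfg$scoring$nstart <- 3L
  cfg$evaluation$folds <- 3L
  cfg
}
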