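#' Pruning / screening configuration
#'
#' Parameters for the differential-expression screen and the
#' path-consistency (PC) pruning of the prior network with Gaussian mutual
#' information.
#'
#' @param max_order maximum PC conditioning order, 0 or 1 (default 1).
#' @param cmi_threshold nonnegative MI/CMI threshold in nats (default 0.03);
#'   edges at or below it are removed.
#' @param anova_alpha adjusted p-value cutoff for the one-way ANOVA screen
#'   (default 1e-4).
#' @param adjust_method multiple-testing procedure passed to
#'   [stats::p.adjust()] (default `"BH"`).
#' @return A list of class `prune_config`.
#' @export
prune_config <- function(max_order = 1L, cmi_threshold = 0.03,
                         anova_alpha = 1e-4, adjust_method = "BH") {
  stopifnot(max_order %in% c(0L, 1L), cmi_threshold >= 0,
            anova_alpha > 0, anova_alpha < 1)
  structure(list(max_order = as.integer(max_order),
                 cmi_threshold = cmi_threshold,
                 anova_alpha = anova_alpha,
                 adjust_method = adjust_method),
            class = "prune_config")
}

#' One-way ANOVA screen across temporal stages
#'
#' Vectorized one-way ANOVA of each gene across stage groups, with
#' multiple-testing adjustment. Genes whose within-group variance is zero but
#' whose between-group variance is positive separate perfectly and get p = 0;
#' genes with no variance at all are never selected (p treated as 1).
#'
#' @param expr an [expr_matrix]; every stage must hold at least two samples.
#' @param cfg a [prune_config].
#' @return Tibble with one row per gene: `gene`, `f`, `p`, `p_adj`,
#'   `selected`.
#' @export
anova_filter <- function(expr, cfg = prune_config()) {
  stopifnot(inherits(expr, "expr_matrix"))
  st <- expr$stage_of
  sizes <- tabulate(st, nbins = expr$n_stages)
  if (any(sizes < 2)) {
    abort(sprintf("stage %d has fewer than 2 samples", which(sizes < 2)[1]))
  }
  x <- expr$values
  n <- ncol(x)
  k <- expr$n_stages
  grand <- rowMeans(x)
  ssb <- numeric(nrow(x))
  ssw <- numeric(nrow(x))
  for (t in seq_len(k)) {
    xt <- x[, st == t, drop = FALSE]
    mt <- rowMeans(xt)
    ssb <- ssb + ncol(xt) * (mt - grand)^2
    ssw <- ssw + rowSums((xt - mt)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  tot <- ssb + ssw
  eps <- 1e-12 * pmax(tot, 1)
  p[ssw <= eps & ssb > eps] <- 0        # perfect separation
  p[tot <= 1e-300] <- 1                 # no variance at all
  f[tot <= 1e-300] <- NA_real_
  p_adj <- p.adjust(p, method = cfg$adjust_method)
  tibble(gene = expr$gene_ids, f = unname(f), p = unname(p),
         p_adj = unname(p_adj),
         selected = unname(p_adj < cfg$anova_alpha & !(tot <= 1e-300)))
}

#' Merge differential and prior disease gene sets
#'
#' @param deg character vector of differentially expressed genes.
#' @param prior_disease character vector of prior disease genes (may be
#'   empty).
#' @return Tibble `gene`, `source` with source in
#'   `{"DEG","prior_disease","both"}`, sorted by gene.
#' @export
assemble_candidates <- function(deg, prior_disease = character()) {
  deg <- unique(normalize_symbols(deg))
  prior_disease <- unique(normalize_symbols(prior_disease))
  genes <- sort(union(deg, prior_disease))
  if (length(genes) == 0) abort("no candidate genes")
  source <- dplyr::case_when(
    genes %in% deg & genes %in% prior_disease ~ "both",
    genes %in% deg ~ "DEG",
    TRUE ~ "prior_disease"
  )
  tibble(gene = genes, source = source)
}

#' Map candidate genes onto the prior network
#'
#' Node-induced subgraph of the prior interaction network on the candidate
#' genes, with isolated mapped genes dropped (logged). The result is the
#' "original network" from which every stage-specific network is carved.
#'
#' @param candidates tibble from [assemble_candidates()] or a character
#'   vector of genes.
#' @param prior igraph prior network.
#' @return igraph network (no isolated nodes).
#' @export
map_to_prior <- function(candidates, prior) {
  genes <- if (is.character(candidates)) candidates else candidates$gene
  genes <- intersect(normalize_symbols(genes), igraph::V(prior)$name)
  if (length(genes) == 0) abort("no candidate gene maps onto the prior network")
  g <- igraph::induced_subgraph(prior, genes)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  if (length(iso) > 0) {
    dnb_log("dropping %d isolated mapped gene(s)", length(iso))
    g <- igraph::delete_vertices(g, iso)
  }
  if (igraph::vcount(g) == 0) abort("original network is empty after isolate removal")
  make_network(igraph::V(g)$name, network_edges(g)[, c("from", "to")])
}

#' Gaussian mutual information between two sample vectors
#'
#' `MI = 1/2 * log( var(x) var(y) / det cov(x,y) )`, the mutual information
#' of a bivariate normal; equals `-1/2 * log(1 - rho^2)` and is zero iff the
#' sample correlation is zero. Returned in nats, clipped at 0.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return Nonnegative scalar; `Inf` when the two vectors are affinely
#'   dependent (including both constant).
#' @export
gaussian_mi <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) abort("x and y must share length n >= 3")
  vx <- var(x); vy <- var(y)
  tol <- 1e-12
  if (vx <= tol || vy <= tol) {
    # a constant vector is affinely related only to another constant vector
    if (vx <= tol && vy <= tol) return(Inf)
    abort("zero variance in one argument of gaussian_mi")
  }
  r <- cor(x, y)
  if (1 - r^2 <= tol) return(Inf)
  max(0, -0.5 * log(1 - r^2))
}

#' Gaussian conditional mutual information CMI(x, y | z)
#'
#' Determinant form
#' `1/2 * log( det C(x,z) det C(y,z) / ( var(z) det C(x,y,z) ) )`, clipped at
#' 0. When z carries all of x's (or y's) variance (e.g. `z = x`) the CMI is 0
#' by convention.
#'
#' @param x,y,z numeric vectors of equal length; `z` must be non-constant.
#' @return Nonnegative scalar.
#' @export
gaussian_cmi <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n || n < 4) {
    abort("x, y, z must share length n >= 4")
  }
  if (var(z) <= 1e-12) abort("conditioning variable z is constant")
  C <- stats::cov(cbind(x = x, y = y, z = z))
  dxz <- C["x", "x"] * C["z", "z"] - C["x", "z"]^2
  dyz <- C["y", "y"] * C["z", "z"] - C["y", "z"]^2
  d3 <- det(C)
  scale <- max(diag(C))^3 + 1e-300
  tol <- 1e-12 * scale
  if (dxz <= tol || dyz <= tol) return(0)  # z determines x or y: nothing left
  if (d3 <= tol) {
    abort("singular covariance in gaussian_cmi: x and y are affinely dependent given z")
  }
  max(0, 0.5 * log(dxz * dyz / (C["z", "z"] * d3)))
}

#' Path-consistency pruning of a network with Gaussian (C)MI
#'
#' Order-0 pass: remove edges whose marginal Gaussian MI over the stage's
#' samples is at or below `cfg$cmi_threshold`. Order-1 pass (if
#' `cfg$max_order >= 1`): for each surviving edge, compute the CMI given each
#' common neighbor in the order-0-surviving graph and remove the edge when
#' the minimum falls at or below the threshold. Both passes are synchronous
#' (evaluated against a fixed graph state) and visit edges in sorted
#' canonical order, so the result is deterministic.
#'
#' @param values_stage genes x samples numeric matrix for one stage (rownames
#'   must cover the network's nodes).
#' @param net igraph network to prune.
#' @param cfg a [prune_config].
#' @return igraph network on the same node set with a subset of the edges.
#' @export
pc_cmi_prune <- function(values_stage, net, cfg = prune_config()) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% rownames(values_stage))) {
    abort("every network node needs an expression row in this stage")
  }
  edges <- network_edges(net)[, c("from", "to")]
  if (nrow(edges) == 0) return(make_network(nodes, edges))
  mi <- vapply(seq_len(nrow(edges)), function(i) {
    gaussian_mi(values_stage[edges$from[i], ], values_stage[edges$to[i], ])
  }, numeric(1))
  edges <- edges[mi > cfg$cmi_threshold, , drop = FALSE]
  if (cfg$max_order >= 1 && nrow(edges) > 0) {
    g0 <- make_network(nodes, edges)
    adj <- igraph::adjacent_vertices(g0, igraph::V(g0))
    names(adj) <- igraph::V(g0)$name
    adj <- lapply(adj, function(v) igraph::V(g0)$name[as.integer(v)])
    keep <- vapply(seq_len(nrow(edges)), function(i) {
      a <- edges$from[i]; b <- edges$to[i]
      common <- intersect(adj[[a]], adj[[b]])
      common <- sort(setdiff(common, c(a, b)))
      if (length(common) == 0) return(TRUE)
      cmis <- vapply(common, function(z) {
        gaussian_cmi(values_stage[a, ], values_stage[b, ], values_stage[z, ])
      }, numeric(1))
      min(cmis) > cfg$cmi_threshold
    }, logical(1))
    edges <- edges[keep, , drop = FALSE]
  }
  make_network(nodes, edges)
}

#' Weight network edges by Pearson correlation
#'
#' Annotates each edge with the signed Pearson correlation of its two genes
#' over the stage's samples. A constant gene yields weight 0 with a warning.
#'
#' @inheritParams pc_cmi_prune
#' @param stage stage ordinal stored on the result.
#' @return igraph network with an edge `weight` attribute in `[-1, 1]` and a
#'   graph attribute `stage`.
#' @export
weight_edges_pcc <- function(values_stage, net, stage = NA_integer_) {
  edges <- network_edges(net)[, c("from", "to")]
  if (nrow(edges) > 0) {
    w <- vapply(seq_len(nrow(edges)), function(i) {
      x <- values_stage[edges$from[i], ]
      y <- values_stage[edges$to[i], ]
      if (var(x) <= 1e-12 || var(y) <= 1e-12) {
        warn(sprintf("constant gene on edge %s-%s: weight set to 0",
                     edges$from[i], edges$to[i]))
        return(0)
      }
      cor(x, y)
    }, numeric(1))
    edges$weight <- w
  } else {
    edges$weight <- double()
  }
  g <- make_network(igraph::V(net)$name, edges)
  igraph::graph_attr(g, "stage") <- as.integer(stage)
  g
}

#' Build the original network and all stage-specific networks
#'
#' Runs the ANOVA screen, merges in prior disease genes, maps the candidates
#' onto the prior interaction network ("original network"), then per stage
#' applies PC pruning and Pearson edge weighting. All stage networks share
#' the original network's node set; nodes that lose every edge at a stage are
#' kept as isolated nodes so per-node quantities stay comparable across
#' stages.
#'
#' @param expr an [expr_matrix].
#' @param prior igraph prior interaction network.
#' @param prior_disease character vector of prior disease genes (optional).
#' @param cfg a [prune_config].
#' @return List with `original` (igraph), `stage_nets` (list of T weighted
#'   igraphs), `candidates` (tibble with source tags) and `anova` (full screen
#'   table).
#' @export
build_stage_networks <- function(expr, prior, prior_disease = character(),
                                 cfg = prune_config()) {
  screen <- anova_filter(expr, cfg)
  deg <- screen$gene[screen$selected]
  candidates <- assemble_candidates(deg, prior_disease)
  original <- map_to_prior(candidates, prior)
  nodes <- igraph::V(original)$name
  stage_nets <- lapply(seq_len(expr$n_stages), function(t) {
    vals <- stage_values(expr, t)
    pruned <- pc_cmi_prune(vals[nodes, , drop = FALSE], original, cfg)
    weight_edges_pcc(vals[nodes, , drop = FALSE], pruned, stage = t)
  })
  dnb_log("original network: %d genes, %d edges; stage edges: %s",
          length(nodes), igraph::ecount(original),
          paste(vapply(stage_nets, igraph::ecount, numeric(1)), collapse = "/"))
  list(original = original, stage_nets = stage_nets,
       candidates = candidates, anova = screen)
}
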