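#' Union of stage networks
#'
#' Edge union across stages over the shared node set; each union edge carries
#' weight `max |w|` over the stages where it occurs (reporting only — path
#' searches use hop counts).
#'
#' @param stage_nets list of igraph stage networks with a shared node set.
#' @return igraph network.
#' @export
union_network <- function(stage_nets) {
  nodes <- sort(igraph::V(stage_nets[[1]])$name)
  all_edges <- dplyr::bind_rows(lapply(stage_nets, network_edges))
  if (nrow(all_edges) == 0) return(make_network(nodes, all_edges))
  all_edges$weight[is.na(all_edges$weight)] <- 1
  agg <- all_edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = max(abs(.data$weight)), .groups = "drop")
  make_network(nodes, agg)
}

#' Node-induced subgraph
#'
#' @param genes character vector of genes.
#' @param graph igraph network.
#' @return igraph subgraph induced on `genes` intersected with the graph's
#'   nodes (isolated nodes kept).
#' @export
induced_subgraph_genes <- function(genes, graph) {
  keep <- intersect(sort(unique(normalize_symbols(genes))),
                    igraph::V(graph)$name)
  if (length(keep) == 0) abort("no gene maps onto the graph")
  igraph::induced_subgraph(graph, keep)
}

#' Greedy minimum dominating set
#'
#' Builds a dominating set greedily: repeatedly add the node covering the
#' most currently undominated nodes (a node covers itself and its
#' neighbors), breaking ties by depth-first-search discovery order rooted at
#' the lexicographically smallest node (restarting at the smallest unvisited
#' node for further components). Isolated nodes dominate only themselves and
#' are always included. Domination of the result is asserted before
#' returning.
#'
#' @param graph igraph network (may be disconnected).
#' @return Sorted character vector of dominator gene ids.
#' @export
greedy_min_dominating_set <- function(graph) {
  nodes <- sort(igraph::V(graph)$name)
  n <- length(nodes)
  if (n == 0) return(character())
  g <- igraph::permute(graph, match(igraph::V(graph)$name, nodes))
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, function(v) as.integer(v))
  closed <- lapply(seq_len(n), function(i) unique(c(i, adj[[i]])))
  dfs_rank <- match(seq_len(n),
                    as.integer(igraph::dfs(g, root = 1, unreachable = TRUE)$order))
  dominated <- rep(FALSE, n)
  chosen <- integer()
  while (!all(dominated)) {
    gain <- vapply(seq_len(n), function(i) sum(!dominated[closed[[i]]]), numeric(1))
    gain[chosen] <- -1
    best <- max(gain)
    cand <- which(gain == best)
    pick <- cand[which.min(dfs_rank[cand])]
    chosen <- c(chosen, pick)
    dominated[closed[[pick]]] <- TRUE
  }
  S <- sort(nodes[chosen])
  stopifnot(all(vapply(seq_len(n),
                       function(i) any(closed[[i]] %in% chosen), logical(1))))
  S
}

# lexicographically smallest canonical form of an undirected path
canonical_path <- function(p) if (lex_less(rev(p), p)) rev(p) else p

#' Connect dominators through shortest union-network paths
#'
#' While the dominator-plus-connector set induces more than one component in
#' the union network, the globally shortest union-network path (hop count;
#' ties by lexicographically smallest path) between any two components is
#' found and its interior nodes are added as connectors. Components that are
#' unreachable in the union network stay separate and are flagged.
#'
#' @param dominators character vector of dominator gene ids (non-empty).
#' @param union_graph igraph union network.
#' @param anomaly_genes optional anomaly set recorded in the result's
#'   provenance.
#' @return Object of class `dnb_result`: list with `genes`, `roles` (named
#'   vector, `"dominator"`/`"connector"`), `subnetwork` (induced igraph),
#'   `edges` (tibble), `connected` flag, `n_components`.
#' @export
connect_dominators <- function(dominators, union_graph, anomaly_genes = NULL) {
  if (length(dominators) == 0) abort("no dominator genes supplied")
  dominators <- sort(unique(dominators))
  missing <- setdiff(dominators, igraph::V(union_graph)$name)
  if (length(missing) > 0) {
    abort(paste0("dominator absent from union network: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  current <- dominators
  connectors <- character()
  repeat {
    sub <- igraph::induced_subgraph(union_graph, current)
    comp <- igraph::components(sub)
    if (comp$no <= 1) break
    membership <- setNames(comp$membership, igraph::V(sub)$name)
    comp_sets <- split(names(membership), membership)
    # hop distances between all current nodes in the full union network
    dmat <- igraph::distances(union_graph, v = current, to = current,
                              weights = NA)
    best <- Inf; best_pair <- NULL
    for (a in seq_along(comp_sets)) {
      for (b in seq_along(comp_sets)) {
        if (a >= b) next
        dd <- dmat[comp_sets[[a]], comp_sets[[b]], drop = FALSE]
        m <- min(dd)
        if (is.finite(m) && m < best) best <- m
      }
    }
    if (!is.finite(best)) break  # remaining components are unreachable
    # all endpoint pairs achieving the global minimum, then the
    # lexicographically smallest shortest path among them
    best_path <- NULL
    for (a in seq_along(comp_sets)) {
      for (b in seq_along(comp_sets)) {
        if (a >= b) next
        dd <- dmat[comp_sets[[a]], comp_sets[[b]], drop = FALSE]
        hits <- which(dd == best, arr.ind = TRUE)
        if (nrow(hits) == 0) next
        for (hh in seq_len(nrow(hits))) {
          u <- rownames(dd)[hits[hh, 1]]
          vv <- colnames(dd)[hits[hh, 2]]
          ps <- igraph::all_shortest_paths(union_graph, from = u, to = vv,
                                           weights = NA)$vpaths
          for (p in ps) {
            pn <- canonical_path(igraph::V(union_graph)$name[as.integer(p)])
            if (is.null(best_path) || lex_less(pn, best_path)) best_path <- pn
          }
        }
      }
    }
    interior <- setdiff(best_path, current)
    connectors <- union(connectors, interior)
    current <- sort(union(current, interior))
  }
  sub <- igraph::induced_subgraph(union_graph, current)
  comp <- igraph::components(sub)
  roles <- setNames(ifelse(current %in% dominators, "dominator", "connector"),
                    current)
  structure(
    list(genes = current, roles = roles[order(names(roles))],
         subnetwork = sub, edges = network_edges(sub),
         connected = comp$no == 1, n_components = comp$no,
         dominators = dominators, connectors = sort(connectors),
         anomaly_genes = sort(anomaly_genes %||% character())),
    class = "dnb_result"
  )
}

#' @export
print.dnb_result <- function(x, ...) {
  cat(sprintf("<dnb_result> %d genes (%d dominators, %d connectors), %d edges, %s\n",
              length(x$genes), sum(x$roles == "dominator"),
              sum(x$roles == "connector"), nrow(x$edges),
              if (x$connected) "connected" else
                sprintf("DISCONNECTED (%d components)", x$n_components)))
  invisible(x)
}

#' Extract the connected biomarker core from an anomaly gene set
#'
#' Convenience wrapper: dominating set on the anomaly-induced subgraph of
#' the union network, then shortest-path connection over the full union
#' network (so non-anomalous genes may enter as connectors).
#'
#' @param anomaly_genes character vector (or `dnb_anomalies`).
#' @param union_graph igraph union network.
#' @return A `dnb_result`.
#' @export
extract_dnb_core <- function(anomaly_genes, union_graph) {
  genes <- if (inherits(anomaly_genes, "dnb_anomalies")) anomaly_genes$genes else anomaly_genes
  sub <- induced_subgraph_genes(genes, union_graph)
  doms <- greedy_min_dominating_set(sub)
  connect_dominators(doms, union_graph, anomaly_genes = genes)
}
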