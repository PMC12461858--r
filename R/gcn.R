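#' Graph-convolution embedding configuration
#'
#' @param d embedding dimension (default 32).
#' @param n_layers number of graph-convolution layers (default 2); ReLU after
#'   every layer except the last, which is linear.
#' @param eta Adam learning rate (default 0.001, the standard Adam step
#'   size; small steps also keep the independently trained per-stage models
#'   near their shared seeded initialization, which preserves cross-stage
#'   comparability of the embeddings).
#' @param epochs training iterations (default 100).
#' @param seed integer seed governing the target embedding, weight
#'   initialization and the train/test node split.
#' @param split_fraction train share of nodes (default 0.8); the held-out
#'   share is only used to monitor test loss — every node gets an embedding.
#' @param use_edge_weights if TRUE (default) the adjacency uses `|w|` for
#'   edge entries; otherwise all edges count 1.
#' @return A list of class `gcn_config`.
#' @export
gcn_config <- function(d = 32L, n_layers = 2L, eta = 0.001, epochs = 100L,
                       seed = 1L, split_fraction = 0.8,
                       use_edge_weights = TRUE) {
  stopifnot(d >= 1, n_layers >= 1, eta > 0, epochs >= 0,
            split_fraction > 0, split_fraction <= 1)
  structure(list(d = as.integer(d), n_layers = as.integer(n_layers),
                 eta = eta, epochs = as.integer(epochs),
                 seed = as.integer(seed), split_fraction = split_fraction,
                 use_edge_weights = isTRUE(use_edge_weights)),
            class = "gcn_config")
}

#' Symmetrically normalized adjacency matrix
#'
#' `A_norm = D^-1/2 (A + I) D^-1/2` where `A` holds `|w_ij|` (or 1 when edge
#' weights are off) for edges and the self-loop entries are 1; `D` is the
#' degree matrix of the self-looped adjacency. Isolated nodes reduce to
#' identity rows.
#'
#' @param net igraph network (node order taken from sorted vertex names).
#' @param use_edge_weights use `|weight|` edge entries when available.
#' @return Symmetric N x N matrix with node dimnames.
#' @export
normalize_adjacency <- function(net, use_edge_weights = TRUE) {
  nodes <- sort(igraph::V(net)$name)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ed <- network_edges(net)
  if (nrow(ed) > 0) {
    w <- if (use_edge_weights && !all(is.na(ed$weight))) abs(ed$weight) else rep(1, nrow(ed))
    A[cbind(ed$from, ed$to)] <- w
    A[cbind(ed$to, ed$from)] <- w
  }
  diag(A) <- 1
  dinv <- 1 / sqrt(rowSums(A))
  A * (dinv %o% dinv)
}

#' Forward pass of the graph-convolution model
#'
#' Applies `H <- A_norm %*% H %*% W[[l]]` for each layer, with ReLU after
#' every layer except the last (the last layer is linear so the output can
#' match a zero-mean Gaussian target).
#'
#' @param H0 N x d input matrix.
#' @param A_norm normalized adjacency from [normalize_adjacency()].
#' @param weights list of d x d layer weight matrices.
#' @return N x d output matrix.
#' @export
gcn_forward <- function(H0, A_norm, weights) {
  if (nrow(H0) != nrow(A_norm)) abort("H0 and A_norm disagree on N")
  H <- H0
  L <- length(weights)
  for (l in seq_len(L)) {
    if (!all(dim(weights[[l]]) == c(ncol(H), ncol(weights[[l]])))) {
      abort(sprintf("layer %d weight shape mismatch", l))
    }
    H <- A_norm %*% H %*% weights[[l]]
    if (l < L) H <- pmax(H, 0)
  }
  H
}

# forward keeping per-layer activations, for backprop
gcn_forward_cache <- function(H0, A_norm, weights) {
  L <- length(weights)
  Hs <- vector("list", L + 1)  # post-activation outputs; Hs[[1]] = H0
  Ms <- vector("list", L)      # ReLU masks (pre-activation > 0)
  Hs[[1]] <- H0
  for (l in seq_len(L)) {
    pre <- A_norm %*% Hs[[l]] %*% weights[[l]]
    if (l < L) {
      Ms[[l]] <- pre > 0
      Hs[[l + 1]] <- pre * Ms[[l]]
    } else {
      Hs[[l + 1]] <- pre
    }
  }
  list(Hs = Hs, Ms = Ms)
}

#' Train the embedding model for one stage network
#'
#' The target embedding `E` is drawn once from a seeded standard normal
#' (scaled by `1/sqrt(d)`) in canonical (sorted-gene) node order; it serves
#' both as the input features `H(0)` and as the regression target, and it is
#' never updated — only the layer weights are trained, by full-batch Adam on
#' the mean squared error over the training nodes. Node-indexed randomness
#' (target rows, train/test split) is keyed to sorted gene ids, so relabeled
#' node orders yield equivariant results.
#'
#' @param net igraph stage network.
#' @param cfg a [gcn_config].
#' @return Object of class `gcn_embedding`: list with `H` (N x d final
#'   embedding, rows named by gene), `E_target`, `node_order`,
#'   `final_train_loss`, `final_test_loss`, `initial_train_loss`, `weights`,
#'   `stage`.
#' @export
train_stage_embedding <- function(net, cfg = gcn_config()) {
  nodes <- sort(igraph::V(net)$name)
  n <- length(nodes)
  d <- cfg$d
  A <- normalize_adjacency(net, cfg$use_edge_weights)

  set.seed(derive_seed(cfg$seed, "target"))
  E <- matrix(rnorm(n * d) / sqrt(d), n, d, dimnames = list(nodes, NULL))

  set.seed(derive_seed(cfg$seed, "weights"))
  W <- lapply(seq_len(cfg$n_layers), function(l) {
    matrix(rnorm(d * d) / sqrt(d), d, d)
  })

  set.seed(derive_seed(cfg$seed, "split"))
  n_train <- max(1L, round(cfg$split_fraction * n))
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)

  loss_on <- function(H, idx) {
    if (length(idx) == 0) return(NA_real_)
    mean(rowSums((H[idx, , drop = FALSE] - E[idx, , drop = FALSE])^2))
  }

  # Adam state
  m <- lapply(W, function(w) w * 0)
  v <- lapply(W, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  L <- cfg$n_layers

  cache <- gcn_forward_cache(E, A, W)
  initial_train_loss <- loss_on(cache$Hs[[L + 1]], train_idx)
  final_train_loss <- initial_train_loss

  if (cfg$epochs > 0) {
    mask <- matrix(0, n, d)
    mask[train_idx, ] <- 1
    for (epoch in seq_len(cfg$epochs)) {
      cache <- gcn_forward_cache(E, A, W)
      H_out <- cache$Hs[[L + 1]]
      G <- (2 / length(train_idx)) * (H_out - E) * mask
      grads <- vector("list", L)
      for (l in rev(seq_len(L))) {
        AH <- A %*% cache$Hs[[l]]
        grads[[l]] <- crossprod(AH, G)
        if (l > 1) {
          G <- (A %*% (G %*% t(W[[l]]))) * cache$Ms[[l - 1]]
        }
      }
      for (l in seq_len(L)) {
        m[[l]] <- b1 * m[[l]] + (1 - b1) * grads[[l]]
        v[[l]] <- b2 * v[[l]] + (1 - b2) * grads[[l]]^2
        mhat <- m[[l]] / (1 - b1^epoch)
        vhat <- v[[l]] / (1 - b2^epoch)
        W[[l]] <- W[[l]] - cfg$eta * mhat / (sqrt(vhat) + eps)
      }
      final_train_loss <- loss_on(gcn_forward(E, A, W), train_idx)
      if (!is.finite(final_train_loss)) abort("training diverged; reduce eta")
    }
  }
  H <- gcn_forward(E, A, W)
  structure(
    list(H = H, E_target = E, node_order = nodes,
         initial_train_loss = initial_train_loss,
         final_train_loss = final_train_loss,
         final_test_loss = loss_on(H, test_idx),
         weights = W, stage = igraph::graph_attr(net, "stage") %||% NA_integer_),
    class = "gcn_embedding"
  )
}

#' @export
print.gcn_embedding <- function(x, ...) {
  cat(sprintf("<gcn_embedding> stage %s: %d nodes x %d dims; train loss %.4f -> %.4f (test %.4f)\n",
              x$stage, nrow(x$H), ncol(x$H), x$initial_train_loss,
              x$final_train_loss, x$final_test_loss))
  invisible(x)
}

#' Embed every stage network
#'
#' Trains one model per stage. All stages share the same seeded target
#' embedding and node order, so a node's vectors are comparable across
#' stages; identical stage networks therefore produce identical embeddings.
#'
#' @param stage_nets list of igraph stage networks over a shared node set.
#' @param cfg a [gcn_config].
#' @return List of `gcn_embedding` objects, one per stage.
#' @export
embed_all_stages <- function(stage_nets, cfg = gcn_config()) {
  node_sets <- lapply(stage_nets, function(g) sort(igraph::V(g)$name))
  if (length(unique(node_sets)) != 1) abort("stage networks must share one node set")
  lapply(seq_along(stage_nets), function(t) {
    emb <- train_stage_embedding(stage_nets[[t]], cfg)
    if (is.na(emb$stage)) emb$stage <- t
    emb
  })
}
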