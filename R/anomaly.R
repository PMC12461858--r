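#' K-means clustering of a stage embedding
#'
#' Seeded multi-restart Lloyd/Hartigan-Wong k-means on the node vectors. At
#' convergence each cluster center equals the coordinate-wise mean of its
#' member vectors.
#'
#' @param emb a `gcn_embedding` (or any N x d matrix with row names).
#' @param k number of clusters, `1 <= k <= N`.
#' @param seed integer seed.
#' @param nstart random restarts (default 10).
#' @return Object of class `dnb_clusters`: list with `assignment` (named
#'   integer vector), `centers` (k x d), `representatives` (k gene ids),
#'   `stage`, `k`, `tot_withinss`.
#' @export
kmeans_cluster <- function(emb, k, seed = 1L, nstart = 10L) {
  H <- if (inherits(emb, "gcn_embedding")) emb$H else emb
  n <- nrow(H)
  if (k > n) abort(sprintf("k = %d exceeds the number of nodes (%d)", k, n))
  if (k < 1) abort("k must be >= 1")
  if (k == n) {
    # every node its own cluster: centers are the node vectors themselves
    fit <- list(cluster = seq_len(n), centers = H, tot.withinss = 0)
  } else {
    set.seed(derive_seed(seed, "kmeans"))
    fit <- kmeans(H, centers = k, nstart = nstart, iter.max = 100L)
  }
  assignment <- setNames(fit$cluster, rownames(H))
  model <- structure(
    list(assignment = assignment, centers = fit$centers, k = k,
         stage = if (inherits(emb, "gcn_embedding")) emb$stage else NA_integer_,
         tot_withinss = fit$tot.withinss),
    class = "dnb_clusters"
  )
  model$representatives <- select_representatives(model, H)
  model
}

#' Representative node of each cluster
#'
#' For each cluster, the member node with the smallest Euclidean distance to
#' the cluster center; ties broken by the lexicographically smallest gene id.
#'
#' @param model a `dnb_clusters` object.
#' @param emb the embedding the model was fitted on (`gcn_embedding` or
#'   matrix).
#' @return Character vector of k gene ids, ordered by cluster index.
#' @export
select_representatives <- function(model, emb) {
  H <- if (inherits(emb, "gcn_embedding")) emb$H else emb
  vapply(seq_len(model$k), function(j) {
    members <- sort(names(model$assignment)[model$assignment == j])
    dd <- sqrt(rowSums((H[members, , drop = FALSE] -
                          matrix(model$centers[j, ], length(members),
                                 ncol(H), byrow = TRUE))^2))
    members[which.min(dd)]  # which.min takes the first (lexicographic) tie
  }, character(1))
}

#' Choose k by the elbow of the within-cluster sum of squares
#'
#' Fits seeded k-means over `k_min..k_max` and returns the interior k
#' maximizing the second difference of the total within-cluster sum of
#' squares curve (the sharpest knee). A range with fewer than three values
#' returns `k_min`.
#'
#' @param emb embedding (`gcn_embedding` or matrix).
#' @param k_min,k_max inclusive search range.
#' @param seed integer seed.
#' @param nstart restarts per k.
#' @return Selected k (integer).
#' @export
choose_k_elbow <- function(emb, k_min, k_max, seed = 1L, nstart = 10L) {
  H <- if (inherits(emb, "gcn_embedding")) emb$H else emb
  stopifnot(k_min <= k_max, k_max <= nrow(H))
  ks <- seq.int(k_min, k_max)
  if (length(ks) < 3) return(as.integer(k_min))
  wss <- vapply(ks, function(k) {
    kmeans_cluster(H, k, seed = derive_seed(seed, paste0("elbow", k)),
                   nstart = nstart)$tot_withinss
  }, numeric(1))
  d2 <- wss[1:(length(ks) - 2)] - 2 * wss[2:(length(ks) - 1)] + wss[3:length(ks)]
  as.integer(ks[which.max(d2) + 1L])
}

#' Outlier scores at the next stage
#'
#' Score of node i at stage t+1 = the minimum Euclidean distance between its
#' stage-(t+1) vector and the stage-(t+1) vectors of the stage-t cluster
#' representatives (representatives are chosen at t but re-evaluated at t+1).
#'
#' @param emb_next `gcn_embedding` for stage t+1.
#' @param reps character vector of representative gene ids from stage t.
#' @return Tibble `gene`, `score`, `stage` (the scored stage), sorted by
#'   gene.
#' @export
outlier_scores <- function(emb_next, reps) {
  if (length(reps) == 0) abort("no representative nodes supplied")
  H <- emb_next$H
  missing <- setdiff(reps, rownames(H))
  if (length(missing) > 0) {
    abort(paste0("representatives absent from embedding: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  d2 <- rep(Inf, nrow(H))
  for (r in reps) {
    d2 <- pmin(d2, rowSums(sweep(H, 2, H[r, ])^2))
  }
  score <- sqrt(d2)
  tibble(gene = rownames(H), score = unname(score),
         stage = emb_next$stage %||% NA_integer_)
}

#' Collect per-stage anomaly genes
#'
#' Per scored stage, the `ceiling(q * N)` highest-scoring genes are taken,
#' with all ties at the cutoff score included; the anomaly set is the union
#' across stages.
#'
#' @param tables list of outlier-score tibbles (one per scored stage, i.e.
#'   stages `2..T`).
#' @param q selection fraction in `(0, 1]`.
#' @return Object of class `dnb_anomalies`: list with `genes` (sorted union),
#'   `per_stage` (named list of per-stage hit sets), `q` and `scores` (the
#'   row-bound score table).
#' @export
collect_anomalies <- function(tables, q) {
  stopifnot(q > 0, q <= 1)
  per_stage <- lapply(tables, function(tb) {
    n_sel <- ceiling(q * nrow(tb))
    ord <- order(-tb$score, tb$gene)
    cutoff <- tb$score[ord[n_sel]]
    sort(tb$gene[tb$score >= cutoff])
  })
  names(per_stage) <- vapply(tables, function(tb) as.character(tb$stage[1]),
                             character(1))
  structure(
    list(genes = sort(unique(unlist(per_stage))), per_stage = per_stage,
         q = q, scores = dplyr::bind_rows(tables)),
    class = "dnb_anomalies"
  )
}

#' @export
print.dnb_anomalies <- function(x, ...) {
  cat(sprintf("<dnb_anomalies> %d genes (q = %g) over stages %s\n",
              length(x$genes), x$q, paste(names(x$per_stage), collapse = ",")))
  invisible(x)
}
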