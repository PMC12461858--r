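#' Community entropy of a module in a stage network
#'
#' `CE = -(g / D_union) * log2(D_module / D_union)` where `g` is the sum of
#' `|w|` over the stage network's boundary edges (exactly one endpoint in the
#' module), `D_module` the total unweighted degree of module nodes in the
#' stage network, and `D_union` the total unweighted degree of the union
#' network. `CE` is defined as 0 when `g = 0` (the 0*log0 guard), so the
#' derived index `DNI = exp(-CE)` stays in `(0, 1]`.
#'
#' @param module character vector of module genes (subset of the node set).
#' @param stage_net igraph stage network (edge weights used for `g`).
#' @param union_graph igraph union network (degrees used for `D_union`).
#' @return One-row tibble: `g_alpha`, `d_alpha`, `d_union`, `ce`, `dni`.
#' @export
community_entropy <- function(module, stage_net, union_graph) {
  module <- intersect(sort(unique(module)), igraph::V(stage_net)$name)
  d_union <- sum(igraph::degree(union_graph))
  if (d_union == 0) abort("empty union graph")
  ed <- network_edges(stage_net)
  in_mod_from <- ed$from %in% module
  in_mod_to <- ed$to %in% module
  boundary <- xor(in_mod_from, in_mod_to)
  w <- ifelse(is.na(ed$weight), 1, abs(ed$weight))
  g_alpha <- sum(w[boundary])
  d_alpha <- sum(igraph::degree(stage_net)[module])
  ce <- if (g_alpha == 0 || d_alpha == d_union) {
    0
  } else {
    -(g_alpha / d_union) * log2(d_alpha / d_union)
  }
  tibble(g_alpha = g_alpha, d_alpha = d_alpha, d_union = d_union,
         ce = ce, dni = exp(-ce))
}

#' Temporal dynamic-network-index curve
#'
#' Evaluates the community entropy of the biomarker module in every stage
#' network and converts it to the dynamic network index `DNI = exp(-CE)`.
#' Rising DNI marks rising disorder of the module's network context; the
#' curve's maximum (earliest stage on ties) flags the putative pre-disease
#' tipping point.
#'
#' @param dnb a `dnb_result` or a character vector of module genes.
#' @param stage_nets list of igraph stage networks.
#' @param union_graph optional precomputed union network (defaults to
#'   [union_network()] of `stage_nets`).
#' @return Object of class `dnb_dni`: tibble with one row per stage
#'   (`stage`, `g_alpha`, `d_alpha`, `d_union`, `ce`, `dni`) plus attribute
#'   `peak_stage`.
#' @export
dni_curve <- function(dnb, stage_nets, union_graph = NULL) {
  module <- if (inherits(dnb, "dnb_result")) dnb$genes else dnb
  union_graph <- union_graph %||% union_network(stage_nets)
  rows <- dplyr::bind_rows(lapply(seq_along(stage_nets), function(t) {
    dplyr::bind_cols(tibble(stage = t),
                     community_entropy(module, stage_nets[[t]], union_graph))
  }))
  peak <- rows$stage[which.max(rows$dni)]  # which.max: earliest tie wins
  structure(rows, peak_stage = peak, module = sort(module),
            class = c("dnb_dni", class(rows)))
}

#' Peak stage of a DNI curve
#' @param x a `dnb_dni` object.
#' @return Integer stage of the DNI maximum (earliest on ties).
#' @export
peak_stage <- function(x) attr(x, "peak_stage")

# rank-based AUROC (Mann-Whitney); 0.5 when a class is empty or scores are
# all tied
auroc_score <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(0.5)
  if (sd(scores) == 0) return(0.5)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# average precision (area under the precision-recall curve, step version)
auprc_score <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0) return(0)
  if (sd(scores) == 0) return(n_pos / length(labels))
  ord <- order(-scores, labels)  # ties: negatives first (conservative)
  lab <- labels[ord]
  tp <- cumsum(lab == 1)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / n_pos
}

classification_metrics <- function(scores, pred, labels) {
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(auroc = auroc_score(scores, labels),
         auprc = auprc_score(scores, labels),
         accuracy = mean(pred == labels),
         f1 = f1, precision = precision, recall = recall)
}

# seeded stratified fold assignment
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_of
}

#' Temporal classification of staged samples by a feature gene set
#'
#' Evaluates how well a gene set separates ordered disease stages: for every
#' split point `s` in `1..T-1`, samples with stage `<= s` are labeled 1 and
#' the rest 0, and a linear-kernel support vector machine with balanced
#' class weights and standardized features is scored by seeded stratified
#' cross-validation (margin scores pooled across folds). AUROC, AUPRC,
#' accuracy, F1, precision and recall are recorded per split and summarized
#' as mean and standard deviation across splits. Splits with fewer than two
#' samples in a class are skipped with a warning.
#'
#' @param expr an [expr_matrix].
#' @param features character vector of feature genes (subset of the
#'   expression genes).
#' @param seed integer seed for fold assignment.
#' @param folds cross-validation folds (default 5).
#' @param cost SVM cost parameter (default 1).
#' @return Object of class `dnb_classification`: list with `per_split`
#'   (tibble, one row per evaluated split) and `summary` (tibble with
#'   `metric`, `mean`, `sd`).
#' @export
temporal_classification <- function(expr, features, seed = 1L, folds = 5L,
                                    cost = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  features <- intersect(sort(unique(normalize_symbols(features))),
                        expr$gene_ids)
  if (length(features) == 0) abort("no feature gene is present in the expression matrix")
  X <- t(expr$values[features, , drop = FALSE])
  st <- expr$stage_of
  splits <- seq_len(expr$n_stages - 1)
  rows <- list()
  for (s in splits) {
    labels <- as.integer(st <= s)
    if (min(table(factor(labels, levels = c(0, 1)))) < 2) {
      warn(sprintf("split %d skipped: a class has fewer than 2 samples", s))
      next
    }
    fold_of <- stratified_folds(labels, folds, derive_seed(seed, paste0("split", s)))
    scores <- numeric(length(labels))
    pred <- integer(length(labels))
    for (f in sort(unique(fold_of))) {
      tr <- fold_of != f
      te <- !tr
      ytr <- factor(labels[tr], levels = c(0, 1))
      if (nlevels(droplevels(ytr)) < 2) {
        scores[te] <- 0; pred[te] <- as.integer(names(which.max(table(ytr))))
        next
      }
      Xtr <- X[tr, , drop = FALSE]
      keep_cols <- apply(Xtr, 2, sd) > 0
      if (!any(keep_cols)) {
        scores[te] <- 0
        pred[te] <- as.integer(names(which.max(table(labels[tr]))))
        next
      }
      cw <- 1 / table(ytr)
      cw <- cw / sum(cw) * 2
      fit <- e1071::svm(Xtr[, keep_cols, drop = FALSE], ytr,
                        kernel = "linear", cost = cost, scale = TRUE,
                        class.weights = cw, probability = FALSE)
      pr <- stats::predict(fit, X[te, keep_cols, drop = FALSE],
                           decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient the margin so larger means class "1"
      if (colnames(attr(pr, "decision.values"))[1] == "0/1") dv <- -dv
      scores[te] <- dv
      pred[te] <- as.integer(as.character(pr))
    }
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(split = s), classification_metrics(scores, pred, labels))
  }
  if (length(rows) == 0) abort("no evaluable temporal split")
  per_split <- dplyr::bind_rows(rows)
  summary <- per_split |>
    tidyr::pivot_longer(-"split", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value) %||% 0, .groups = "drop")
  summary$sd[is.na(summary$sd)] <- 0
  structure(list(per_split = per_split, summary = summary,
                 features = features, folds = folds, seed = seed),
            class = "dnb_classification")
}

#' @export
print.dnb_classification <- function(x, ...) {
  a <- x$summary[x$summary$metric == "auroc", ]
  cat(sprintf("<dnb_classification> %d features, %d split(s): mean AUROC %.3f +/- %.3f\n",
              length(x$features), nrow(x$per_split), a$mean, a$sd))
  invisible(x)
}
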