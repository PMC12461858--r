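#' Configuration for the synthetic staged-expression benchmark
#'
#' The generator emulates pathway-structured bulk expression: genes fall
#' into co-expression blocks ("pathways") of size `block_size` with
#' within-block correlation `rho_bg` and weak across-block correlation
#' `rho_far`. One planted module of size `module_size` has elevated internal
#' correlation `rho_in` and is coupled to a partner pathway at `rho_bg`
#' through `n_boundary` prior edges per module gene. At the critical stage
#' `t_star` the module rewires: internal correlation drops to
#' `rho_in * (1 - delta)` for every stage `>= t_star` (persistent internal
#' reorganization), the module transiently decouples from its partner
#' pathway exactly at `t_star` (boundary correlation `rho_bg * (1 - delta)`,
#' partially recovering afterwards to the largest level consistent with the
#' broken internal structure), and module means drift by
#' `mean_shift_per_stage * delta` per stage from `t_star` onward. With
#' `delta = 0` every stage is identically distributed (a genuine null).
#'
#' Everything is drawn from an explicit latent-factor model (one global
#' factor, one factor per block, one module factor), so the implied
#' correlation matrix is positive definite by construction; configurations
#' whose targets are unreachable (negative residual loadings) fail with
#' advice to lower `rho_in`.
#'
#' @param n_genes number of genes (default 300).
#' @param n_stages number of temporal stages T (default 6).
#' @param n_samples_per_stage samples per stage (default 20).
#' @param module_size size m of the planted module (default 12).
#' @param t_star rewiring stage, `2 <= t_star <= T` (default 3).
#' @param rho_in within-module correlation before rewiring, in `[0, 1)`
#'   (default 0.7).
#' @param rho_bg within-pathway background correlation (default 0.55; high
#'   enough that pathway-backed prior edges are reliably recovered by the
#'   mutual-information prune at the default per-stage sample size, so stage
#'   networks are stable except where the planted rewiring acts). Must
#'   satisfy `rho_in > rho_bg >= 0`.
#' @param delta rewiring strength in `[0, 1]` (default 0.8).
#' @param prior_extra_edges decoy prior edges across pathways, carrying only
#'   the weak `rho_far` correlation — the false-positive regulations the
#'   path-consistency prune exists to remove (default 150).
#' @param block_size pathway size (default 25).
#' @param rho_far across-pathway correlation (default 0.05).
#' @param n_boundary prior edges from each module gene into the partner
#'   pathway (default 2).
#' @param block_density preferential-attachment edges per node in each
#'   pathway's prior subgraph (default 5; curated pathways are locally
#'   dense, and this keeps pathway genes from isolating in a 20-sample
#'   stage by pruning chance alone).
#' @param mean_shift_per_stage module mean drift per stage step after
#'   `t_star`, scaled by `delta` (default 0.5 log2 units).
#' @param baseline_mean baseline log2 expression level (default 8).
#' @param seed integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 300L, n_stages = 6L,
                             n_samples_per_stage = 20L, module_size = 12L,
                             t_star = 3L, rho_in = 0.7, rho_bg = 0.55,
                             delta = 0.8, prior_extra_edges = 150L,
                             block_size = 25L, rho_far = 0.05,
                             n_boundary = 2L, block_density = 5L,
                             mean_shift_per_stage = 0.5,
                             baseline_mean = 8, seed = 1L) {
  stopifnot(module_size < n_genes, t_star >= 2, t_star <= n_stages,
            n_stages >= 2, rho_in > rho_bg, rho_bg >= 0, rho_in < 1,
            rho_bg > rho_far, rho_far >= 0, delta >= 0, delta <= 1,
            n_samples_per_stage >= 2, block_size >= 3,
            n_genes - module_size >= block_size)
  structure(as.list(environment()), class = "synthetic_config")
}

# Factor loadings of module genes for one stage: each module gene is
# sqrt(rho_far)*G + c*F_partner + m*F_module + resid. Solving
#   within-module  = rho_far + c^2 + m^2  = r_mm(t)
#   module-partner = rho_far + c * l_P    = r_mb(t),  l_P = sqrt(rho_bg - rho_far)
# r_mm drops to rho_in*(1-delta) from t_star on; r_mb dips to
# rho_bg*(1-delta) at t_star and afterwards recovers to the largest value
# consistent with the broken internal correlation.
module_loadings <- function(cfg, stage) {
  post <- stage >= cfg$t_star
  l_p <- sqrt(cfg$rho_bg - cfg$rho_far)
  r_mm <- if (post) cfg$rho_in * (1 - cfg$delta) else cfg$rho_in
  r_mb <- if (stage == cfg$t_star) {
    cfg$rho_bg * (1 - cfg$delta)
  } else if (post) {
    min(cfg$rho_bg, cfg$rho_far + sqrt(max(r_mm - cfg$rho_far, 0)) * l_p)
  } else {
    cfg$rho_bg
  }
  c_t <- max(r_mb - cfg$rho_far, 0) / l_p
  m2 <- r_mm - cfg$rho_far - c_t^2
  resid2 <- 1 - cfg$rho_far - c_t^2 - max(m2, 0)
  if (m2 < -1e-9 || resid2 <= 1e-9) {
    abort(sprintf("stage %d module correlation targets are infeasible; lower rho_in or delta",
                  stage))
  }
  list(c = c_t, m = sqrt(max(m2, 0)), resid = sqrt(resid2))
}

# seeded scale-free subgraph on a set of gene names
scale_free_edges <- function(genes, m_attach = 2) {
  n <- length(genes)
  if (n < 2) return(tibble(from = character(), to = character()))
  g <- igraph::sample_pa(n, power = 1, m = min(m_attach, n - 1),
                         directed = FALSE)
  el <- igraph::as_edgelist(g)
  perm <- sample.int(n)  # detach hub identity from gene index
  tibble(from = genes[perm[as.integer(el[, 1])]],
         to = genes[perm[as.integer(el[, 2])]])
}

#' Generate a synthetic staged dataset with a planted rewiring module
#'
#' Draws per-stage expression from the latent-factor model described in
#' [synthetic_config()] and builds a prior interaction network from seeded
#' scale-free subgraphs within each pathway, the planted module clique, the
#' module's boundary edges into its partner pathway, and `prior_extra_edges`
#' across-pathway decoy edges. Fully determined by `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `expr` ([expr_matrix]), `prior` (igraph) and `truth`
#'   (list: `module_genes`, `t_star`, `partner_genes`, `blocks`, `config`).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_genes
  m <- cfg$module_size
  genes <- sprintf("G%04d", seq_len(n))

  set.seed(derive_seed(cfg$seed, "structure"))
  module_genes <- sort(sample(genes, m))
  bg_genes <- setdiff(genes, module_genes)
  n_blocks <- max(1L, round(length(bg_genes) / cfg$block_size))
  block_of_bg <- sort(rep_len(seq_len(n_blocks), length(bg_genes)))
  block_of_bg <- setNames(sample(block_of_bg), sample(bg_genes))
  partner_block <- 1L
  partner_genes <- sort(names(block_of_bg)[block_of_bg == partner_block])

  # prior network: pathway-wise scale-free subgraphs + module clique +
  # boundary edges into the partner pathway + cross-pathway decoys
  edges <- dplyr::bind_rows(lapply(seq_len(n_blocks), function(b) {
    scale_free_edges(sort(names(block_of_bg)[block_of_bg == b]),
                     m_attach = cfg$block_density)
  }))
  clique <- t(utils::combn(module_genes, 2))
  edges <- dplyr::bind_rows(edges, tibble(from = clique[, 1], to = clique[, 2]))
  boundary <- dplyr::bind_rows(lapply(module_genes, function(gm) {
    tibble(from = gm, to = sample(partner_genes, cfg$n_boundary))
  }))
  edges <- dplyr::bind_rows(edges, boundary)
  if (cfg$prior_extra_edges > 0) {
    extra_from <- sample(genes, 3 * cfg$prior_extra_edges, replace = TRUE)
    extra_to <- sample(genes, 3 * cfg$prior_extra_edges, replace = TRUE)
    keep <- extra_from != extra_to
    extra <- head(tibble(from = extra_from[keep], to = extra_to[keep]),
                  cfg$prior_extra_edges)
    edges <- dplyr::bind_rows(edges, extra)
  }
  prior <- make_network(genes, edges)

  # per-stage expression from the latent-factor model
  ns <- cfg$n_samples_per_stage
  values <- matrix(NA_real_, n, cfg$n_stages * ns,
                   dimnames = list(genes, NULL))
  sample_ids <- character(cfg$n_stages * ns)
  stage_of <- integer(cfg$n_stages * ns)
  l_bg <- sqrt(cfg$rho_bg - cfg$rho_far)
  resid_bg <- sqrt(1 - cfg$rho_bg)
  set.seed(derive_seed(cfg$seed, "expression"))
  for (tt in seq_len(cfg$n_stages)) {
    ld <- module_loadings(cfg, tt)
    G <- rnorm(ns)                       # global factor
    Fb <- matrix(rnorm(ns * n_blocks), ns, n_blocks)  # pathway factors
    Fm <- rnorm(ns)                      # module factor
    X <- matrix(NA_real_, ns, n, dimnames = list(NULL, genes))
    for (b in seq_len(n_blocks)) {
      gb <- names(block_of_bg)[block_of_bg == b]
      X[, gb] <- sqrt(cfg$rho_far) * G + l_bg * Fb[, b] +
        resid_bg * matrix(rnorm(ns * length(gb)), ns)
    }
    X[, module_genes] <- sqrt(cfg$rho_far) * G + ld$c * Fb[, partner_block] +
      ld$m * Fm + ld$resid * matrix(rnorm(ns * m), ns)
    mu <- rep(cfg$baseline_mean, n)
    if (tt >= cfg$t_star) {
      mu[match(module_genes, genes)] <- mu[match(module_genes, genes)] +
        cfg$delta * cfg$mean_shift_per_stage * (tt - cfg$t_star + 1)
    }
    cols <- (tt - 1) * ns + seq_len(ns)
    values[, cols] <- t(X) + mu
    sample_ids[cols] <- sprintf("S%d_%02d", tt, seq_len(ns))
    stage_of[cols] <- tt
  }
  colnames(values) <- sample_ids
  expr <- expr_matrix(values, setNames(stage_of, sample_ids))
  list(expr = expr, prior = prior,
       truth = list(module_genes = module_genes, t_star = cfg$t_star,
                    partner_genes = partner_genes,
                    blocks = block_of_bg, config = cfg))
}

#' Set-overlap recovery of the planted module
#'
#' @param predicted character vector of predicted genes.
#' @param truth the `truth` element from [generate_synthetic()] (or a
#'   character vector of true module genes).
#' @return One-row tibble: `precision`, `recall`, `f1`, `n_predicted`,
#'   `n_true`, `empty_prediction` flag (precision reported as 0 when nothing
#'   was predicted).
#' @export
recovery_score <- function(predicted, truth) {
  true_genes <- if (is.list(truth)) truth$module_genes else truth
  predicted <- unique(predicted)
  tp <- length(intersect(predicted, true_genes))
  empty <- length(predicted) == 0
  precision <- if (empty) 0 else tp / length(predicted)
  recall <- tp / length(true_genes)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1,
         n_predicted = length(predicted), n_true = length(true_genes),
         empty_prediction = empty)
}
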