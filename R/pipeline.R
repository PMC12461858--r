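#' Default run configuration
#'
#' Nested configuration for the full pipeline, overridable from a YAML file
#' via [read_run_config()]. Defaults follow the reference analysis settings:
#' 100 training epochs, 8:2 node split, elbow-selected cluster count, top 1%
#' anomaly fraction.
#'
#' @param seed global seed; every stochastic stage derives its own seed from
#'   it.
#' @return Nested list of class `run_config` with blocks `grn`, `gcn`,
#'   `scoring`, `evaluation`, `simulate`, `io`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    io = list(expression = NULL, stage_map = NULL, prior = NULL,
              prior_disease = NULL, dup_policy = "variance"),
    grn = list(max_order = 1L, cmi_threshold = 0.03, anova_alpha = 1e-4,
               adjust_method = "BH", use_all_genes = FALSE),
    gcn = list(d = 32L, n_layers = 2L, eta = 0.001, epochs = 100L,
               split_fraction = 0.8, use_edge_weights = TRUE),
    scoring = list(k = NULL, k_min = 2L, k_max = 24L, q = 0.01,
                   cluster_mode = "per_stage", nstart = 10L),
    evaluation = list(folds = 5L, svm_cost = 1),
    simulate = list(n_genes = 300L, n_stages = 6L, n_samples_per_stage = 20L,
                    module_size = 12L, t_star = 3L, rho_in = 0.7,
                    rho_bg = 0.55, delta = 0.8, prior_extra_edges = 150L,
                    mean_shift_per_stage = 0.5)
  ), class = "run_config")
}

# recursive merge that rejects unknown keys
merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) abort(sprintf("unknown config key '%s'", full))
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], full)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys keep their defaults. The merged
#' configuration is echoed verbatim into the run report.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @param seed optional seed overriding the file's.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
    class(cfg) <- "run_config"
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' Analysis configuration for the planted-module benchmark
#'
#' Mirrors the reference analysis at benchmark scale. The candidate set is
#' the differential screen plus the known disease-pathway gene set, exactly
#' as a real study maps differential genes plus literature disease genes
#' onto the prior network (a working network of roughly a tenth of the
#' panel). Scaled settings, chosen for the benchmark's per-stage sample
#' size and panel size and documented in the methods vignette: a
#' significance-calibrated marginal-independence prune
#' (`cmi_threshold = qchisq(0.95, 1) / (2 * n)` nats at `n = 20` samples per
#' stage, conditioning order 0 because pathway co-membership edges are
#' explained away by shared-factor neighbors at order 1), a lenient ANOVA
#' level (`alpha = 0.05`) suited to a small panel, an anomaly fraction
#' `q = 0.1` sized so one scored stage can flag a module-scale gene set,
#' and an elbow range capped at 15.
#'
#' @param seed global seed.
#' @param n_samples_per_stage per-stage sample size used to calibrate the
#'   prune threshold (default 20, the benchmark condition).
#' @return A `run_config` list.
#' @export
benchmark_config <- function(seed = 1L, n_samples_per_stage = 20L) {
  cfg <- default_config(seed)
  cfg$grn$anova_alpha <- 0.05
  cfg$grn$max_order <- 0L
  cfg$grn$cmi_threshold <- stats::qchisq(0.95, 1) / (2 * n_samples_per_stage)
  cfg$scoring$q <- 0.1
  cfg$scoring$k_max <- 15L
  cfg
}

#' Run the full biomarker-discovery pipeline in memory
#'
#' Builds stage networks, embeds them, scores anomalies, extracts the
#' connected biomarker core, and evaluates it with the DNI curve and
#' temporal classification.
#'
#' @param expr an [expr_matrix].
#' @param prior igraph prior network.
#' @param config a `run_config` (see [default_config()]).
#' @param prior_disease optional character vector of prior disease genes.
#' @return Object of class `dnb_run`: list with `networks`, `embeddings`,
#'   `clusters`, `outliers`, `anomalies`, `result` (`dnb_result`), `dni`
#'   (`dnb_dni`), `classification` (`dnb_classification`), `k`, `config`.
#' @export
dnb_run <- function(expr, prior, config = default_config(),
                    prior_disease = character()) {
  seed <- config$seed
  grn_cfg <- prune_config(max_order = config$grn$max_order,
                          cmi_threshold = config$grn$cmi_threshold,
                          anova_alpha = config$grn$anova_alpha,
                          adjust_method = config$grn$adjust_method)
  if (isTRUE(config$grn$use_all_genes)) {
    prior_disease <- union(prior_disease, igraph::V(prior)$name)
  }
  nets <- build_stage_networks(expr, prior, prior_disease, grn_cfg)

  gcn_cfg <- gcn_config(d = config$gcn$d, n_layers = config$gcn$n_layers,
                        eta = config$gcn$eta, epochs = config$gcn$epochs,
                        seed = derive_seed(seed, "gcn"),
                        split_fraction = config$gcn$split_fraction,
                        use_edge_weights = config$gcn$use_edge_weights)
  embeddings <- embed_all_stages(nets$stage_nets, gcn_cfg)

  k <- config$scoring$k
  if (is.null(k)) {
    k_max <- min(config$scoring$k_max, nrow(embeddings[[1]]$H) - 1L)
    k <- choose_k_elbow(embeddings[[1]], config$scoring$k_min, k_max,
                        seed = derive_seed(seed, "elbow"),
                        nstart = config$scoring$nstart)
    dnb_log("elbow-selected k = %d", k)
  }
  T <- length(embeddings)
  cluster_stages <- if (identical(config$scoring$cluster_mode, "stage_1")) {
    rep(1L, T - 1)
  } else {
    seq_len(T - 1)
  }
  clusters <- list()
  outliers <- list()
  for (i in seq_len(T - 1)) {
    ct <- cluster_stages[i]
    key <- as.character(ct)
    if (is.null(clusters[[key]])) {
      clusters[[key]] <- kmeans_cluster(embeddings[[ct]], k,
                                        seed = derive_seed(seed, paste0("km", ct)),
                                        nstart = config$scoring$nstart)
    }
    outliers[[i]] <- outlier_scores(embeddings[[i + 1]],
                                    clusters[[key]]$representatives)
  }
  anomalies <- collect_anomalies(outliers, config$scoring$q)
  dnb_log("anomaly set: %d genes", length(anomalies$genes))

  union_graph <- union_network(nets$stage_nets)
  result <- extract_dnb_core(anomalies, union_graph)
  dnb_log("DNB core: %d genes (%d dominators), %d edges",
          length(result$genes), length(result$dominators), nrow(result$edges))

  dni <- dni_curve(result, nets$stage_nets, union_graph)
  classification <- temporal_classification(
    expr, result$genes, seed = derive_seed(seed, "svm"),
    folds = config$evaluation$folds, cost = config$evaluation$svm_cost)

  structure(list(networks = nets, embeddings = embeddings,
                 clusters = clusters, outliers = outliers,
                 anomalies = anomalies, result = result, dni = dni,
                 classification = classification, k = k,
                 union_graph = union_graph, config = config),
            class = "dnb_run")
}

#' @export
print.dnb_run <- function(x, ...) {
  cat("== dnbtrace run ==\n")
  print(x$result)
  cat(sprintf("DNI peak at stage %d\n", peak_stage(x$dni)))
  print(x$classification)
  invisible(x)
}

#' Write the discovered biomarker set and its subnetwork
#'
#' Emits `dnb_genes.txt` (gene + role), `dnb_edges.tsv` (weighted edge
#' list) and `report.json` (counts, per-stage scores, config echo, seed).
#'
#' @param result a `dnb_result`.
#' @param out_dir output directory (created if needed).
#' @param config optional `run_config` echoed into the report.
#' @param extra optional named list merged into the report.
#' @return Invisibly, the report list.
#' @export
write_result <- function(result, out_dir, config = NULL, extra = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  }
  readr::write_tsv(tibble(gene = result$genes,
                          role = unname(result$roles[result$genes])),
                   file.path(out_dir, "dnb_genes.txt"), progress = FALSE)
  readr::write_tsv(result$edges, file.path(out_dir, "dnb_edges.tsv"),
                   progress = FALSE)
  report <- c(list(
    n_genes = length(result$genes),
    n_edges = nrow(result$edges),
    n_dominators = length(result$dominators),
    n_connectors = length(result$connectors),
    connected = result$connected,
    n_components = result$n_components,
    empty = length(result$genes) == 0,
    genes = result$genes,
    seed = config$seed %||% NA,
    config = if (is.null(config)) NULL else unclass(config)
  ), extra)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

# ---- artifact-level subcommands -------------------------------------------
# Each subcommand reads its upstream artifacts from `out_dir` and writes its
# own, so `dnb_run_all()` and a chain of subcommands produce byte-identical
# artifact sets.

artifact <- function(out_dir, ...) file.path(out_dir, ...)

require_artifact <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s not found: expected '%s'; run the upstream subcommand first",
                  what, path))
  }
  path
}

#' Pipeline subcommands over serialized artifacts
#'
#' Each function is independently runnable and idempotent given identical
#' inputs; together (simulate/build-nets/embed/score/extract/evaluate) they
#' reproduce [dnb_run_all()] exactly.
#'
#' @param config a `run_config`.
#' @param out_dir artifact directory.
#' @return Invisibly, the subcommand's main artifact (see details of each).
#' @name dnb_cmd
NULL

#' @rdname dnb_cmd
#' @export
dnb_cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- do.call(synthetic_config,
                     c(config$simulate, list(seed = derive_seed(config$seed, "sim"))))
  sim <- generate_synthetic(sim_cfg)
  write_expression(sim$expr, artifact(out_dir, "expression.tsv"),
                   artifact(out_dir, "stage_map.tsv"))
  write_edge_list(sim$prior, artifact(out_dir, "prior.tsv"))
  readr::write_lines(sim$truth$partner_genes,
                     artifact(out_dir, "prior_disease.txt"))
  readr::write_lines(sim$truth$module_genes, artifact(out_dir, "truth_module.txt"))
  readr::write_lines(as.character(sim$truth$t_star), artifact(out_dir, "truth_tstar.txt"))
  invisible(sim)
}

load_inputs <- function(config, out_dir) {
  expr_path <- config$io$expression %||% artifact(out_dir, "expression.tsv")
  map_path <- config$io$stage_map %||% artifact(out_dir, "stage_map.tsv")
  prior_path <- config$io$prior %||% artifact(out_dir, "prior.tsv")
  require_artifact(expr_path, "expression table")
  require_artifact(map_path, "stage map")
  require_artifact(prior_path, "prior network")
  expr <- read_expression(expr_path, map_path,
                          dup_policy = config$io$dup_policy %||% "variance")
  prior <- read_edge_list(prior_path)
  pd_path <- config$io$prior_disease %||% artifact(out_dir, "prior_disease.txt")
  prior_disease <- if (file.exists(pd_path)) read_gene_set(pd_path) else character()
  list(expr = expr, prior = prior, prior_disease = prior_disease)
}

#' @rdname dnb_cmd
#' @export
dnb_cmd_build_nets <- function(config, out_dir) {
  inp <- load_inputs(config, out_dir)
  grn_cfg <- prune_config(max_order = config$grn$max_order,
                          cmi_threshold = config$grn$cmi_threshold,
                          anova_alpha = config$grn$anova_alpha,
                          adjust_method = config$grn$adjust_method)
  prior_disease <- inp$prior_disease
  if (isTRUE(config$grn$use_all_genes)) {
    prior_disease <- union(prior_disease, igraph::V(inp$prior)$name)
  }
  nets <- build_stage_networks(inp$expr, inp$prior, prior_disease, grn_cfg)
  write_edge_list(nets$original, artifact(out_dir, "original.tsv"),
                  nodes_path = artifact(out_dir, "original_nodes.txt"))
  for (t in seq_along(nets$stage_nets)) {
    write_edge_list(nets$stage_nets[[t]],
                    artifact(out_dir, sprintf("stage_%d.tsv", t)))
  }
  readr::write_tsv(nets$candidates, artifact(out_dir, "candidates.tsv"),
                   progress = FALSE)
  readr::write_tsv(nets$anova, artifact(out_dir, "anova.tsv"), progress = FALSE)
  invisible(nets)
}

read_stage_nets <- function(out_dir) {
  nodes_path <- require_artifact(artifact(out_dir, "original_nodes.txt"),
                                 "original network nodes")
  nodes <- readr::read_lines(nodes_path, progress = FALSE)
  paths <- Sys.glob(artifact(out_dir, "stage_*.tsv"))
  paths <- paths[grepl("stage_\\d+\\.tsv$", paths)]
  if (length(paths) == 0) abort("stage networks not found; run build-nets first")
  ts <- as.integer(sub(".*stage_(\\d+)\\.tsv$", "\\1", paths))
  lapply(sort(ts), function(t) {
    ed <- readr::read_tsv(artifact(out_dir, sprintf("stage_%d.tsv", t)),
                          show_col_types = FALSE, progress = FALSE)
    g <- make_network(nodes, ed)
    igraph::graph_attr(g, "stage") <- t
    g
  })
}

#' @rdname dnb_cmd
#' @export
dnb_cmd_embed <- function(config, out_dir) {
  stage_nets <- read_stage_nets(out_dir)
  gcn_cfg <- gcn_config(d = config$gcn$d, n_layers = config$gcn$n_layers,
                        eta = config$gcn$eta, epochs = config$gcn$epochs,
                        seed = derive_seed(config$seed, "gcn"),
                        split_fraction = config$gcn$split_fraction,
                        use_edge_weights = config$gcn$use_edge_weights)
  embeddings <- embed_all_stages(stage_nets, gcn_cfg)
  for (t in seq_along(embeddings)) {
    emb <- embeddings[[t]]
    df <- dplyr::bind_cols(tibble(gene = emb$node_order),
                           as_tibble(emb$H, .name_repair = ~ paste0("v", seq_along(.x))))
    readr::write_tsv(df, artifact(out_dir, sprintf("embedding_%d.tsv", t)),
                     progress = FALSE)
  }
  losses <- tibble(
    stage = seq_along(embeddings),
    initial_train_loss = vapply(embeddings, `[[`, numeric(1), "initial_train_loss"),
    final_train_loss = vapply(embeddings, `[[`, numeric(1), "final_train_loss"),
    final_test_loss = vapply(embeddings, `[[`, numeric(1), "final_test_loss"))
  readr::write_tsv(losses, artifact(out_dir, "embedding_losses.tsv"),
                   progress = FALSE)
  invisible(embeddings)
}

read_embeddings <- function(out_dir) {
  paths <- Sys.glob(artifact(out_dir, "embedding_*.tsv"))
  paths <- paths[grepl("embedding_\\d+\\.tsv$", paths)]
  if (length(paths) == 0) abort("embeddings not found; run embed first")
  ts <- as.integer(sub(".*embedding_(\\d+)\\.tsv$", "\\1", paths))
  lapply(sort(ts), function(t) {
    df <- readr::read_tsv(artifact(out_dir, sprintf("embedding_%d.tsv", t)),
                          show_col_types = FALSE, progress = FALSE)
    H <- as.matrix(df[, -1, drop = FALSE])
    rownames(H) <- df$gene
    structure(list(H = H, node_order = df$gene, stage = t),
              class = "gcn_embedding")
  })
}

#' @rdname dnb_cmd
#' @export
dnb_cmd_score <- function(config, out_dir) {
  embeddings <- read_embeddings(out_dir)
  seed <- config$seed
  k <- config$scoring$k
  if (is.null(k)) {
    k_max <- min(config$scoring$k_max, nrow(embeddings[[1]]$H) - 1L)
    k <- choose_k_elbow(embeddings[[1]], config$scoring$k_min, k_max,
                        seed = derive_seed(seed, "elbow"),
                        nstart = config$scoring$nstart)
  }
  T <- length(embeddings)
  cluster_stages <- if (identical(config$scoring$cluster_mode, "stage_1")) {
    rep(1L, T - 1)
  } else {
    seq_len(T - 1)
  }
  clusters <- list()
  outliers <- list()
  for (i in seq_len(T - 1)) {
    ct <- cluster_stages[i]
    key <- as.character(ct)
    if (is.null(clusters[[key]])) {
      clusters[[key]] <- kmeans_cluster(embeddings[[ct]], k,
                                        seed = derive_seed(seed, paste0("km", ct)),
                                        nstart = config$scoring$nstart)
    }
    outliers[[i]] <- outlier_scores(embeddings[[i + 1]],
                                    clusters[[key]]$representatives)
  }
  anomalies <- collect_anomalies(outliers, config$scoring$q)
  score_tab <- anomalies$scores |>
    tidyr::pivot_wider(names_from = "stage", values_from = "score",
                       names_prefix = "stage_")
  readr::write_tsv(score_tab, artifact(out_dir, "outlier_scores.tsv"),
                   progress = FALSE)
  hits <- dplyr::bind_rows(lapply(names(anomalies$per_stage), function(s) {
    tibble(gene = anomalies$per_stage[[s]], stage = as.integer(s))
  })) |>
    dplyr::mutate(hit = 1L) |>
    tidyr::pivot_wider(names_from = "stage", values_from = "hit",
                       values_fill = 0L, names_prefix = "stage_")
  readr::write_tsv(hits, artifact(out_dir, "anomaly_genes.tsv"), progress = FALSE)
  readr::write_lines(as.character(k), artifact(out_dir, "k_selected.txt"))
  invisible(anomalies)
}

#' @rdname dnb_cmd
#' @export
dnb_cmd_extract <- function(config, out_dir) {
  hits_path <- require_artifact(artifact(out_dir, "anomaly_genes.tsv"),
                                "anomaly gene set")
  anomaly_genes <- readr::read_tsv(hits_path, show_col_types = FALSE,
                                   progress = FALSE)$gene
  stage_nets <- read_stage_nets(out_dir)
  union_graph <- union_network(stage_nets)
  write_edge_list(union_graph, artifact(out_dir, "union.tsv"))
  result <- extract_dnb_core(anomaly_genes, union_graph)
  write_result(result, out_dir, config = config)
  invisible(result)
}

#' @rdname dnb_cmd
#' @export
dnb_cmd_evaluate <- function(config, out_dir) {
  genes_path <- require_artifact(artifact(out_dir, "dnb_genes.txt"), "DNB gene list")
  genes <- readr::read_tsv(genes_path, show_col_types = FALSE, progress = FALSE)$gene
  stage_nets <- read_stage_nets(out_dir)
  inp <- load_inputs(config, out_dir)
  dni <- dni_curve(genes, stage_nets)
  readr::write_tsv(as_tibble(dni), artifact(out_dir, "dni_curve.tsv"),
                   progress = FALSE)
  readr::write_lines(as.character(peak_stage(dni)),
                     artifact(out_dir, "dni_peak_stage.txt"))
  cls <- temporal_classification(inp$expr, genes,
                                 seed = derive_seed(config$seed, "svm"),
                                 folds = config$evaluation$folds,
                                 cost = config$evaluation$svm_cost)
  readr::write_tsv(cls$per_split, artifact(out_dir, "classification_splits.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(summary = cls$summary, per_split = cls$per_split,
         dni_peak_stage = peak_stage(dni)),
    artifact(out_dir, "classification.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(dni = dni, classification = cls))
}

#' Run every pipeline stage against an artifact directory
#'
#' Sequentially invokes the subcommands (optionally `simulate` first when no
#' input files are configured), so the artifact set equals what the
#' subcommands produce individually.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @param out_dir artifact directory.
#' @param simulate generate synthetic inputs first (default: TRUE when no
#'   expression path is configured).
#' @return Invisibly, a list with the `dnb_result`, `dni`, `classification`.
#' @export
dnb_run_all <- function(config, out_dir,
                        simulate = is.null(config$io$expression)) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (simulate) dnb_cmd_simulate(config, out_dir)
  dnb_cmd_build_nets(config, out_dir)
  dnb_cmd_embed(config, out_dir)
  dnb_cmd_score(config, out_dir)
  result <- dnb_cmd_extract(config, out_dir)
  ev <- dnb_cmd_evaluate(config, out_dir)
  invisible(list(result = result, dni = ev$dni,
                 classification = ev$classification))
}
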