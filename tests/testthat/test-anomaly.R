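fake_embedding <- function(H, stage = 2L) {
  structure(list(H = H, node_order = rownames(H), stage = stage),
            class = "gcn_embedding")
}

test_that("k-means fixtures: degenerate k and exact two-cluster centers", {
  H <- matrix(c(0, 0, 0, 1, 10, 10, 10, 11), 4, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  # k = N: every node its own cluster, zero within-cluster scatter
  full <- kmeans_cluster(H, 4, seed = 1)
  expect_equal(full$tot_withinss, 0)
  expect_equal(sort(unname(full$assignment)), 1:4)
  # k = 1: single center is the grand mean
  one <- kmeans_cluster(H, 1, seed = 1)
  expect_equal(unname(one$centers[1, ]), colMeans(H), ignore_attr = TRUE)
  # k = 2: the exhaustive optimum splits {A,B} vs {C,D}
  two <- kmeans_cluster(H, 2, seed = 1)
  cents <- two$centers[order(two$centers[, 1]), ]
  expect_equal(unname(cents), rbind(c(0, 0.5), c(10, 10.5)))
  expect_error(kmeans_cluster(H, 5, seed = 1), "exceeds")
})

test_that("cluster centers equal member means at convergence", {
  set.seed(8)
  H <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(sprintf("G%02d", 1:60), NULL))
  model <- kmeans_cluster(H, 6, seed = 3)
  for (j in 1:6) {
    members <- names(model$assignment)[model$assignment == j]
    expect_gt(length(members), 0)
    expect_equal(unname(model$centers[j, ]),
                 unname(colMeans(H[members, , drop = FALSE])), tolerance = 1e-10)
  }
})

test_that("representatives are nearest members with lexicographic ties", {
  H <- rbind(A = c(0, 0), B = c(1, 0), C = c(3, 0))
  model <- list(assignment = c(A = 1L, B = 1L, C = 1L),
                centers = matrix(c(0.5, 0), 1, 2), k = 1L)
  expect_equal(select_representatives(model, H), "A")  # dist .5 vs .5 vs 2.5: tie A/B
  model$centers <- matrix(c(0.9, 0), 1, 2)
  expect_equal(select_representatives(model, H), "B")  # B strictly closer
  singleton <- list(assignment = c(Z = 1L), centers = matrix(c(9, 9), 1, 2), k = 1L)
  expect_equal(select_representatives(singleton, rbind(Z = c(0, 0))), "Z")
})

test_that("the elbow finds well-separated blobs and handles degenerate ranges", {
  set.seed(12)
  blob <- function(cx, cy) cbind(rnorm(20, cx, 0.1), rnorm(20, cy, 0.1))
  H <- rbind(blob(0, 0), blob(10, 0), blob(5, 8))
  rownames(H) <- sprintf("G%02d", 1:60)
  expect_equal(choose_k_elbow(H, 1, 8, seed = 5), 3L)
  expect_equal(choose_k_elbow(H, 3, 3, seed = 5), 3L)
  # featureless data: any interior k, but reproducibly the same one
  set.seed(13)
  H0 <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(sprintf("G%02d", 1:40), NULL))
  k1 <- choose_k_elbow(H0, 2, 8, seed = 7)
  expect_identical(k1, choose_k_elbow(H0, 2, 8, seed = 7))
  expect_true(k1 >= 2 && k1 <= 8)
})

test_that("outlier scores are next-stage distances to representative nodes", {
  H <- rbind(A = c(0, 0), B = c(3, 4), C = c(10, 0), D = c(1, 0))
  emb <- fake_embedding(H)
  # a representative scores zero on itself
  expect_equal(outlier_scores(emb, c("A"))$score[1], 0)
  # single representative at origin: node B at (3,4) -> distance 5
  sc <- outlier_scores(emb, "A")
  expect_equal(sc$score[sc$gene == "B"], 5)
  # two representatives: min over both
  sc2 <- outlier_scores(emb, c("A", "C"))
  expect_equal(sc2$score[sc2$gene == "D"], 1)
  expect_error(outlier_scores(emb, character()), "no representative")
  expect_error(outlier_scores(emb, "ZZ"), "absent")
})

test_that("outlier scores equal the brute-force double loop and ignore rep order", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(10:50, 1)
    H <- matrix(rnorm(n * 6), n, 6, dimnames = list(sprintf("G%02d", 1:n), NULL))
    reps <- sample(rownames(H), sample(2:8, 1))
    sc <- outlier_scores(fake_embedding(H), reps)
    brute <- vapply(rownames(H), function(g) {
      min(vapply(reps, function(r) sqrt(sum((H[g, ] - H[r, ])^2)), numeric(1)))
    }, numeric(1))
    expect_equal(sc$score, unname(brute[sc$gene]), tolerance = 1e-12)
    sc_rev <- outlier_scores(fake_embedding(H), rev(reps))
    expect_equal(sc_rev$score, sc$score)
  }
})

test_that("anomaly collection uses ceilings, expands ties, and is monotone in q", {
  tb <- tibble::tibble(gene = c("A", "B", "C", "D"),
                       score = c(5, 4, 4, 1), stage = 2L)
  got <- collect_anomalies(list(tb), q = 0.5)  # ceil(2) = 2, tie at 4 expands
  expect_equal(got$per_stage[["2"]], c("A", "B", "C"))
  all_of_them <- collect_anomalies(list(tb), q = 1)
  expect_equal(all_of_them$genes, sort(tb$gene))
  # ceiling arithmetic at q = 0.01, N = 500
  set.seed(3)
  big <- tibble::tibble(gene = sprintf("G%03d", 1:500), score = rnorm(500),
                        stage = 2L)
  expect_equal(length(collect_anomalies(list(big), 0.01)$per_stage[["2"]]), 5L)
  # monotonicity in q, per stage
  prev <- character()
  for (q in c(0.01, 0.05, 0.2, 1)) {
    cur <- collect_anomalies(list(big), q)$per_stage[["2"]]
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # union across stages
  tb3 <- tibble::tibble(gene = c("A", "B", "C", "D"), score = c(1, 5, 2, 0),
                        stage = 3L)
  both <- collect_anomalies(list(tb, tb3), 0.25)
  expect_equal(both$genes, c("A", "B"))
  expect_equal(names(both$per_stage), c("2", "3"))
})

test_that("rewired-module genes outscore the background at the crash stage", {
  wins <- 0L
  for (s in 1:6) {
    sim <- generate_synthetic(synthetic_config(
      n_genes = 120L, module_size = 8L, n_stages = 3L, t_star = 2L,
      block_size = 20L, seed = 300 + s))
    cfg <- benchmark_config(seed = 300 + s)
    pc <- prune_config(max_order = cfg$grn$max_order,
                       cmi_threshold = cfg$grn$cmi_threshold,
                       anova_alpha = cfg$grn$anova_alpha)
    nets <- suppressMessages(build_stage_networks(
      sim$expr, sim$prior,
      union(sim$truth$partner_genes, sim$truth$module_genes), pc))
    embs <- embed_all_stages(nets$stage_nets, gcn_config(d = 16, seed = s))
    cm <- kmeans_cluster(embs[[1]], 5, seed = s)
    sc <- outlier_scores(embs[[2]], cm$representatives)
    mod <- intersect(sim$truth$module_genes, sc$gene)
    med_mod <- stats::median(sc$score[sc$gene %in% mod])
    med_bg <- stats::median(sc$score[!sc$gene %in% mod])
    if (med_mod > med_bg) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})
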