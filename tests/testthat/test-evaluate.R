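test_that("community entropy matches the hand-evaluated path fixture", {
  pg <- toy_graph(c("A", "B", "C"), c("B", "C", "D"), weight = c(1, 1, 1))
  ce <- community_entropy(c("A", "B"), pg, pg)
  expect_equal(ce$g_alpha, 1)       # the single B-C boundary edge
  expect_equal(ce$d_alpha, 3)
  expect_equal(ce$d_union, 6)
  expect_equal(ce$ce, 1 / 6)
  expect_equal(ce$dni, exp(-1 / 6))
})

test_that("community entropy guards: no boundary, whole-graph module", {
  tri <- toy_graph(c("A", "B", "C"), c("B", "C", "A"), weight = c(.5, .5, .5))
  iso <- toy_graph("A", "B", weight = 1, nodes = c("A", "B", "C", "D"))
  # module with no boundary edges
  none <- community_entropy(c("C", "D"), iso, iso)
  expect_equal(none$ce, 0)
  expect_equal(none$dni, 1)
  # module = entire graph
  all_of_it <- community_entropy(c("A", "B", "C"), tri, tri)
  expect_equal(all_of_it$ce, 0)
  edgeless <- toy_graph(character(), character(), nodes = c("A", "B"))
  expect_error(community_entropy("A", edgeless, edgeless), "empty union")
})

test_that("community entropy equals a brute-force edge classification oracle", {
  for (s in 1:8) {
    g <- random_graph(sample(6:15, 1), stats::runif(1, 0.2, 0.6), 900 + s)
    set.seed(s)
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g), -1, 1)
    module <- sample(igraph::V(g)$name, sample(2:4, 1))
    got <- community_entropy(module, g, g)
    # oracle: enumerate edges, classify, then evaluate the formula directly
    ed <- igraph::as_edgelist(g)
    w <- abs(igraph::E(g)$weight)
    inm <- matrix(ed %in% module, ncol = 2)
    g_alpha <- sum(w[xor(inm[, 1], inm[, 2])])
    d_alpha <- sum(ed %in% module)
    d_union <- 2 * nrow(ed)
    ce <- if (g_alpha == 0 || d_alpha == d_union) 0 else
      -(g_alpha / d_union) * log2(d_alpha / d_union)
    expect_equal(got$g_alpha, g_alpha, tolerance = 1e-12)
    expect_equal(got$d_alpha, d_alpha)
    expect_equal(got$ce, ce, tolerance = 1e-12)
    expect_equal(got$dni, exp(-ce), tolerance = 1e-12)
    expect_gt(got$dni, 0); expect_lte(got$dni, 1)
  }
})

test_that("the DNI curve reports one record per stage with an earliest-tie peak", {
  g <- toy_graph(c("A", "B", "C"), c("B", "C", "D"), weight = c(1, 1, 1))
  flat <- dni_curve(c("A", "B"), list(g, g, g))
  expect_equal(nrow(flat), 3L)
  expect_equal(length(unique(flat$dni)), 1L)
  expect_equal(peak_stage(flat), 1L)
  # a stage where the module loses all boundary edges has DNI 1, the maximum
  g_cut <- toy_graph("A", "B", weight = 1, nodes = c("A", "B", "C", "D"))
  curve <- dni_curve(c("A", "B"), list(g, g_cut, g))
  expect_equal(curve$dni[2], 1)
  expect_equal(peak_stage(curve), 2L)
})

test_that("a stage-ordinal feature classifies every temporal split perfectly", {
  T <- 4; per <- 8
  vals <- matrix(rep(rep(1:T, each = per), 2), nrow = 2, byrow = TRUE)
  vals[2, ] <- vals[2, ] + 0.01 * seq_len(T * per)  # break exact ties
  expr <- toy_expr(vals, rep(1:T, each = per))
  rep <- temporal_classification(expr, c("G01", "G02"), seed = 1, folds = 4)
  expect_equal(nrow(rep$per_split), T - 1)
  expect_true(all(rep$per_split$auroc == 1))
  expect_equal(rep$summary$sd[rep$summary$metric == "auroc"], 0)
})

test_that("a constant feature yields AUROC 0.5 by convention", {
  vals <- rbind(rep(5, 24), rep(1:2, 12))
  expr <- toy_expr(vals, rep(1:3, each = 8))
  rep <- temporal_classification(expr, "G01", seed = 2, folds = 3)
  expect_true(all(rep$per_split$auroc == 0.5))
})

test_that("stage-independent features hover near chance", {
  aurocs <- vapply(1:5, function(s) {
    set.seed(s)
    vals <- matrix(rnorm(6 * 160), 6, 160)
    expr <- toy_expr(vals, rep(1:4, each = 40))
    rep <- temporal_classification(expr, sprintf("G%02d", 1:6),
                                   seed = s, folds = 4)
    rep$summary$mean[rep$summary$metric == "auroc"]
  }, numeric(1))
  expect_true(all(abs(aurocs - 0.5) <= 0.15))
})

test_that("classification reports are reproducible and metrics in range", {
  set.seed(30)
  vals <- matrix(rnorm(5 * 36), 5, 36)
  vals[1, ] <- vals[1, ] + rep(c(0, 0.5, 1.2), each = 12)
  expr <- toy_expr(vals, rep(1:3, each = 12))
  r1 <- temporal_classification(expr, sprintf("G%02d", 1:5), seed = 4, folds = 3)
  r2 <- temporal_classification(expr, sprintf("G%02d", 1:5), seed = 4, folds = 3)
  expect_identical(r1$per_split, r2$per_split)
  long <- tidyr::pivot_longer(r1$per_split, -split)
  expect_true(all(long$value >= 0 & long$value <= 1))
  # a split with an under-populated class is skipped with a warning
  tiny <- toy_expr(matrix(rnorm(2 * 13), 2, 13), c(1, rep(2, 6), rep(3, 6)))
  expect_warning(rep3 <- temporal_classification(tiny, c("G01", "G02"),
                                                 seed = 1, folds = 3),
                 "skipped")
  expect_equal(nrow(rep3$per_split), 1L)
})

test_that("adding an uninformative gene barely moves a separable AUROC", {
  set.seed(31)
  T <- 4; per <- 10
  sig <- rep(1:T, each = per) + 0.2 * rnorm(T * per)
  noise <- rnorm(T * per)
  expr <- toy_expr(rbind(sig, sig + 0.1 * rnorm(T * per), noise),
                   rep(1:T, each = per))
  base <- temporal_classification(expr, c("G01", "G02"), seed = 6, folds = 4)
  with_noise <- temporal_classification(expr, c("G01", "G02", "G03"),
                                        seed = 6, folds = 4)
  a0 <- base$summary$mean[base$summary$metric == "auroc"]
  a1 <- with_noise$summary$mean[with_noise$summary$metric == "auroc"]
  expect_lte(a1 - a0, 0.05)
})
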