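test_that("the ANOVA screen handles degenerate and hand-computable genes", {
  vals <- rbind(c(5, 5, 5, 5, 5, 5),       # constant -> never selected
                c(0, 0, 0, 1, 1, 1),       # perfect separation -> p = 0
                c(1, 2, 3, 2, 3, 4))       # ordinary gene
  expr <- toy_expr(vals, c(1, 1, 1, 2, 2, 2))
  out <- anova_filter(expr, prune_config(anova_alpha = 0.05))
  out <- out[match(c("G01", "G02", "G03"), out$gene), ]
  expect_false(out$selected[1])
  expect_equal(out$p[2], 0)
  expect_true(out$selected[2])
  # oracle: stats::aov on the third gene
  df <- data.frame(y = vals[3, ], g = factor(c(1, 1, 1, 2, 2, 2)))
  f_ref <- summary(stats::aov(y ~ g, df))[[1]]$`F value`[1]
  expect_equal(out$f[3], f_ref, tolerance = 1e-12)
})

test_that("a stage with fewer than 2 samples is fatal", {
  expr <- toy_expr(matrix(rnorm(12), 4, 3), c(1, 1, 2))
  expect_error(anova_filter(expr), "fewer than 2 samples")
})

test_that("candidate assembly tags sources by set membership", {
  got <- assemble_candidates(c("A", "B"), c("B", "C"))
  expect_equal(got$source[match(c("A", "B", "C"), got$gene)],
               c("DEG", "both", "prior_disease"))
  expect_true(all(assemble_candidates(c("A", "B"))$source == "DEG"))
  dis <- assemble_candidates(sprintf("D%d", 1:5), sprintf("P%d", 1:3))
  expect_equal(nrow(dis), 8L)
  expect_equal(sum(dis$source == "both"), 0L)
})

test_that("mapping candidates onto the prior keeps the connected induced part", {
  prior <- toy_graph(c("A", "B", "C", "C"), c("B", "C", "A", "D"))
  full <- map_to_prior(c("A", "B", "C", "D"), prior)
  expect_equal(igraph::ecount(full), igraph::ecount(prior))
  tri <- map_to_prior(c("A", "B", "C"), prior)
  expect_equal(igraph::vcount(tri), 3L)
  expect_equal(igraph::ecount(tri), 3L)
  path <- toy_graph(c("A", "B"), c("B", "C"))
  expect_error(suppressMessages(map_to_prior(c("A", "C"), path)), "empty")
})

test_that("Gaussian MI matches the closed form and the independence limit", {
  # population MI at rho = 0.6
  set.seed(4)
  x <- rnorm(5000); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(5000)
  expect_equal(gaussian_mi(x, y), -0.5 * log(1 - 0.36), tolerance = 0.03)
  # independence: MI below 0.03 in nearly all seeds at n = 1000
  hits <- sum(vapply(1:30, function(s) {
    set.seed(s); gaussian_mi(rnorm(1000), rnorm(1000)) < 0.03
  }, logical(1)))
  expect_gte(hits, 28)
  # affine dependence -> infinite
  set.seed(5); x <- rnorm(10)
  expect_equal(gaussian_mi(x, x), Inf)
  expect_equal(gaussian_mi(rep(1, 10), rep(2, 10)), Inf)
  expect_error(gaussian_mi(rep(1, 10), rnorm(10)), "zero variance")
  expect_true(gaussian_mi(x, rnorm(10)) >= 0)
})

test_that("Gaussian CMI: conditioning on x removes x, chains are blocked", {
  set.seed(6)
  x <- rnorm(200); z <- x + 0.3 * rnorm(200); y <- z + 0.3 * rnorm(200)
  expect_equal(gaussian_cmi(x, y, x), 0)
  # Markov chain: x independent of y given z, at n = 500
  hits <- sum(vapply(1:30, function(s) {
    set.seed(s)
    x <- rnorm(500); z <- x + 0.5 * rnorm(500); y <- z + 0.5 * rnorm(500)
    gaussian_cmi(x, y, z) < 0.03
  }, logical(1)))
  expect_gte(hits, 28)
})

test_that("Gaussian CMI agrees with a residual-regression oracle", {
  for (s in 1:5) {
    set.seed(s)
    z <- rnorm(300)
    x <- 0.5 * z + rnorm(300)
    y <- -0.3 * z + 0.4 * x + rnorm(300)
    rx <- stats::resid(stats::lm(x ~ z))
    ry <- stats::resid(stats::lm(y ~ z))
    oracle <- -0.5 * log(1 - stats::cor(rx, ry)^2)
    expect_equal(gaussian_cmi(x, y, z), oracle, tolerance = 1e-2)
  }
})

test_that("MI and CMI are symmetric in x and y", {
  set.seed(9)
  x <- rnorm(100); y <- 0.4 * x + rnorm(100); z <- 0.2 * y + rnorm(100)
  expect_equal(gaussian_mi(x, y), gaussian_mi(y, x))
  expect_equal(gaussian_cmi(x, y, z), gaussian_cmi(y, x, z))
})

test_that("PC pruning removes indirect edges and respects structure", {
  tri <- toy_graph(c("X", "Z", "X"), c("Z", "Y", "Y"))
  # chain data: X -> Z -> Y; the X-Y edge is indirect
  set.seed(11)
  x <- rnorm(500); z <- x + 0.5 * rnorm(500); y <- z + 0.5 * rnorm(500)
  vals <- rbind(X = x, Y = y, Z = z)
  pruned <- pc_cmi_prune(vals, tri, prune_config(max_order = 1, cmi_threshold = 0.03))
  ed <- network_edges(pruned)
  expect_equal(nrow(ed), 2L)
  expect_false(any(ed$from == "X" & ed$to == "Y"))
  # threshold 0: nothing removed (all MIs finite positive)
  expect_equal(igraph::ecount(pc_cmi_prune(vals, tri,
                 prune_config(max_order = 0, cmi_threshold = 0))), 3L)
  # 2-node network: order-1 pass is a structural no-op
  two <- toy_graph("X", "Z")
  expect_equal(igraph::ecount(pc_cmi_prune(vals, two, prune_config(max_order = 1,
                 cmi_threshold = 0.03))), 1L)
})

test_that("pruning is monotone in the threshold", {
  set.seed(13)
  vals <- matrix(rnorm(8 * 40), 8, 40,
                 dimnames = list(sprintf("N%02d", 1:8), NULL))
  vals[2, ] <- vals[1, ] + 0.5 * rnorm(40)
  g <- random_graph(8, 0.5, 13)
  prev <- NULL
  for (tau in c(0, 0.02, 0.05, 0.1, 0.3)) {
    ed <- network_edges(pc_cmi_prune(vals, g, prune_config(cmi_threshold = tau)))
    key <- paste(ed$from, ed$to)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("edge weights are the Pearson correlation over stage samples", {
  g <- toy_graph("A", "B")
  w1 <- network_edges(weight_edges_pcc(rbind(A = 1:3, B = c(2, 4, 6)), g))$weight
  expect_equal(w1, 1)
  w2 <- network_edges(weight_edges_pcc(rbind(A = 1:3, B = 3:1), g))$weight
  expect_equal(w2, -1)
  w3 <- network_edges(weight_edges_pcc(rbind(A = 1:4, B = c(1, 3, 2, 4)), g))$weight
  expect_equal(w3, 0.8)
  expect_warning(
    w0 <- network_edges(weight_edges_pcc(rbind(A = 1:3, B = c(2, 2, 2)), g))$weight,
    "constant")
  expect_equal(w0, 0)
})

test_that("stage-network construction is deterministic and threshold-limited", {
  set.seed(17)
  base <- matrix(rnorm(10 * 8), 10, 8)
  vals <- cbind(base, base)  # two identical stages
  expr <- toy_expr(vals, rep(1:2, each = 8))
  prior <- random_graph(10, 0.5, 17)
  igraph::V(prior)$name <- sprintf("G%02d", 1:10)
  prior <- dnbtrace:::make_network(sprintf("G%02d", 1:10),
                                   network_edges(prior)[, 1:2])
  cfg <- prune_config(anova_alpha = 0.5, cmi_threshold = 0.01)
  nets <- suppressMessages(
    build_stage_networks(expr, prior, sprintf("G%02d", 1:10), cfg))
  expect_equal(network_edges(nets$stage_nets[[1]]),
               network_edges(nets$stage_nets[[2]]))
  expect_identical(sort(igraph::V(nets$stage_nets[[1]])$name),
                   sort(igraph::V(nets$original)$name))
  # a huge threshold leaves only isolated nodes
  cfg2 <- prune_config(anova_alpha = 0.5, cmi_threshold = 50)
  nets2 <- suppressMessages(
    build_stage_networks(expr, prior, sprintf("G%02d", 1:10), cfg2))
  expect_true(all(vapply(nets2$stage_nets, igraph::ecount, numeric(1)) == 0))
  expect_equal(igraph::vcount(nets2$stage_nets[[1]]), igraph::vcount(nets$original))
})
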