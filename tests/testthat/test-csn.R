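test_that("null draws are rank differences of distinct positions", {
  null2 <- empirical_null(c(g1 = 1, g2 = 2), n_shuffles = 500, seed = 1)
  expect_true(all(null2$samples %in% c(-1, 1)))

  tied <- empirical_null(rep(2.5, 4), n_shuffles = 200, seed = 1)
  expect_true(all(tied$samples == 0))

  a <- empirical_null(c(3, 1, 4, 2), n_shuffles = 1000, seed = 99)
  b <- empirical_null(c(3, 1, 4, 2), n_shuffles = 1000, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$n_shuffles, 1000)

  expect_error(empirical_null(5), class = "drm_degenerate_error")
})

test_that("the closed-form null pmf matches exhaustive pair enumeration", {
  for (m in 2:7) {
    pmf <- analytic_null_pmf(m)
    pairs <- expand.grid(a = 1:m, b = 1:m)
    pairs <- pairs[pairs$a != pairs$b, ]
    want <- table(factor(pairs$a - pairs$b, levels = pmf$delta)) / nrow(pairs)
    expect_equal(pmf$prob, as.numeric(want), tolerance = 1e-12)
    expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  }
  pmf3 <- analytic_null_pmf(3)
  expect_equal(pmf3$prob[pmf3$delta == 1], 1 / 3)
  expect_equal(pmf3$prob[pmf3$delta == -2], 1 / 6)
  expect_error(analytic_null_pmf(1), class = "drm_validation_error")
})

test_that("the shuffle null is statistically indistinguishable from the pmf", {
  m <- 50
  null <- empirical_null(sample(m), n_shuffles = 10000, seed = 7)
  pmf <- analytic_null_pmf(m)
  counts <- table(factor(null$samples, levels = pmf$delta))
  # goodness of fit against the exact pmf; a biased sampler (e.g. one
  # admitting a == b) fails this decisively
  gof <- suppressWarnings(stats::chisq.test(as.numeric(counts), p = pmf$prob))
  expect_gt(gof$p.value, 0.001)
  tv <- 0.5 * sum(abs(as.numeric(counts) / null$n_shuffles - pmf$prob))
  exp_tv <- 0.5 * sum(sqrt(2 * pmf$prob * (1 - pmf$prob) / (pi * 10000)))
  expect_lt(tv, 3 * exp_tv)
})

test_that("empirical p-values use the add-one two-sided count", {
  null <- structure(list(samples = c(rep(2, 5), rep(0, 5)), n_shuffles = 10,
                         m = 10, seed = 1, source_cell = NULL),
                    class = "null_distribution")
  expect_equal(empirical_pvalue(1, null), 6 / 11)
  expect_equal(empirical_pvalue(0, null), 1)
  expect_equal(empirical_pvalue(99, null), 1 / 11)

  big <- empirical_null(1:200, n_shuffles = 10000, seed = 1)
  expect_equal(empirical_pvalue(1e6, big), 1 / 10001)
  expect_equal(empirical_pvalue(0, big), 1)
})

test_that("cell-specific networks keep exactly the sub-alpha edges", {
  # all network genes tied -> every delta 0 -> empty network
  ranks <- stats::setNames(rep(3.5, 6), paste0("g", 1:6))
  net <- tiny_net(c("g1", "g3"), c("g2", "g4"))
  csn <- cell_specific_network(ranks, net, n_shuffles = 500, seed = 2)
  expect_identical(nrow(csn$edges), 0L)

  # an edge joining the unique top and bottom gene is maximally extreme
  m <- 100
  ranks2 <- stats::setNames(as.numeric(sample(m)), paste0("g", 1:m))
  top <- names(ranks2)[which.max(ranks2)]
  bottom <- names(ranks2)[which.min(ranks2)]
  net2 <- tiny_net(top, bottom)
  csn2 <- cell_specific_network(ranks2, net2, n_shuffles = 2000, seed = 3)
  expect_identical(nrow(csn2$edges), 1L)
  expect_identical(csn2$edges$delta, m - 1)
  expect_equal(csn2$edges$p_value, 1 / 2001)

  # alpha = 0 can keep nothing
  csn3 <- cell_specific_network(ranks2, net2, n_shuffles = 200, alpha = 0, seed = 3)
  expect_identical(nrow(csn3$edges), 0L)

  # deterministic function of (ranks, net, seed, N, alpha)
  csn4 <- cell_specific_network(ranks2, net2, n_shuffles = 2000, seed = 3)
  expect_identical(csn4$edges, csn2$edges)
})

test_that("random edges are called significant at about the alpha rate", {
  set.seed(10)
  m <- 300
  ranks <- stats::setNames(as.numeric(sample(m)), paste0("g", 1:m))
  a <- sample(names(ranks), 1000, replace = TRUE)
  b <- sample(names(ranks), 1000, replace = TRUE)
  keep <- a != b
  k <- paste(pmin(a, b), pmax(a, b))
  keep <- keep & !duplicated(k)
  net <- tiny_net(a[keep], b[keep])
  csn <- cell_specific_network(ranks, net, n_shuffles = 10000, alpha = 0.05,
                               seed = 11)
  frac <- nrow(csn$edges) / nrow(net)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("cell-type networks average raw deltas per edge", {
  sim <- simulate_gem(n_types = 2, cells_per_type = 4, n_genes = 30,
                      n_edges = 40, n_marker_edges_per_type = 3, seed = 12)
  drm <- build_drm(sim$expression, sim$network)
  tn <- cell_type_network(drm, sim$labels, "T1")
  cells_t1 <- names(sim$labels)[sim$labels == "T1"]
  expect_equal(tn$mean_delta,
               unname(rowMeans(drm$raw[, cells_t1])), tolerance = 1e-12)

  one <- cell_type_network(drm$raw[, 1, drop = FALSE], "T1", "T1")
  expect_equal(one$mean_delta, unname(drm$raw[, 1]), tolerance = 1e-12)

  x <- matrix(c(3, -3), 1, 2, dimnames = list("a|b", c("c1", "c2")))
  expect_identical(cell_type_network(x, c("t", "t"), "t")$mean_delta, 0)

  expect_error(cell_type_network(drm, sim$labels, "T9"),
               class = "drm_validation_error")
})

test_that("common patterns report per-edge occurrence fractions", {
  net <- tiny_net(c("A", "A", "B"), c("B", "C", "C"))
  csn_with <- function(ids) {
    structure(list(cell_id = "x",
                   edges = data.frame(edge_id = ids,
                                      delta = rep(0, length(ids)),
                                      p_value = rep(0.01, length(ids))),
                   alpha = 0.05, n_shuffles = 10, seed = 1),
              class = "cell_specific_network")
  }
  csns <- list(csn_with("A|B"), csn_with("A|B"), csn_with(c("A|B", "A|C")),
               csn_with(character(0)))
  cp <- common_pattern(csns, "A", net)
  expect_identical(cp$fraction[cp$edge_id == "A|B"], 0.75)
  expect_identical(cp$fraction[cp$edge_id == "A|C"], 0.25)
  expect_identical(nrow(cp), 2L)

  cp_rev <- common_pattern(rev(csns), "A", net)
  expect_identical(cp, cp_rev)

  expect_error(common_pattern(csns, "Z", net), class = "drm_validation_error")
})

test_that("the per-cell wrapper is reproducible per cell across subsets", {
  sim <- simulate_gem(n_types = 2, cells_per_type = 3, n_genes = 40,
                      n_edges = 50, n_marker_edges_per_type = 3, seed = 14)
  all_cells <- cell_specific_networks(sim$expression, sim$network,
                                      n_shuffles = 300, seed = 5)
  some <- cell_specific_networks(sim$expression, sim$network,
                                 cells = names(sim$labels)[c(2, 5)],
                                 n_shuffles = 300, seed = 5)
  expect_identical(some[[1]]$edges, all_cells[[2]]$edges)
  expect_identical(some[[2]]$edges, all_cells[[5]]$edges)
})
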