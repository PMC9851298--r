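test_that("within-cell ranks follow the average-tie convention", {
  gem <- cbind(c1 = c(5, 1, 0, 3), c2 = c(0, 0, 2, 5), c3 = c(4, 4, 4, 4))
  rownames(gem) <- paste0("g", 1:4)
  r <- rank_transform(gem)
  expect_identical(unname(r[, "c1"]), c(4, 2, 1, 3))
  expect_identical(unname(r[, "c2"]), c(1.5, 1.5, 3, 4))
  expect_identical(unname(r[, "c3"]), c(2.5, 2.5, 2.5, 2.5))
  expect_identical(attr(r, "tie_method"), "average")
})

test_that("rank columns always sum to m(m+1)/2 under average ties", {
  for (seed in 1:5) {
    gem <- tiny_gem(m = 7, n = 5, seed = seed, with_ties = TRUE)
    r <- rank_transform(gem)
    expect_equal(unname(colSums(r)), rep(7 * 8 / 2, 5))
  }
})

test_that("delta ranks subtract endpoint ranks in stored orientation", {
  gem <- cbind(c1 = c(9, 5, 1, 7))
  rownames(gem) <- paste0("g", 1:4)
  r <- rank_transform(gem)          # ranks 4, 2, 1, 3
  net <- tiny_net(c("g1", "g3"), c("g4", "g1"))
  d <- delta_rank(r, net)
  expect_identical(unname(d[1, 1]), 4 - 3)
  expect_identical(unname(d[2, 1]), 1 - 4)

  tied <- cbind(c1 = c(0, 0, 2, 5))
  rownames(tied) <- paste0("g", 1:4)
  expect_identical(unname(delta_rank(rank_transform(tied),
                                     tiny_net("g1", "g2"))[1, 1]), 0)

  expect_error(delta_rank(r, tiny_net("g1", "gX")),
               class = "drm_missing_gene_error")
})

test_that("column z-scoring uses the sample sd and zeroes constant columns", {
  expect_equal(zscore_columns(cbind(c(3, -1))), cbind(c(1, -1) / sqrt(2)),
               tolerance = 1e-12)
  expect_identical(unname(zscore_columns(cbind(c(0, 0, 0)))[, 1]), c(0, 0, 0))
  expect_equal(unname(zscore_columns(cbind(1:3))[, 1]), c(-1, 0, 1),
               tolerance = 1e-12)
  expect_error(zscore_columns(matrix(1, 1, 2)), class = "drm_degenerate_error")
})

test_that("edge orientation flip negates raw rows exactly", {
  gem <- tiny_gem(8, 6, seed = 9, with_ties = TRUE)
  net_fwd <- tiny_net(c("g1", "g3", "g5"), c("g2", "g4", "g6"))
  net_rev <- tiny_net(c("g2", "g4", "g6"), c("g1", "g3", "g5"))
  fwd <- build_drm(gem, net_fwd, normalize = FALSE)$raw
  rev <- build_drm(gem, net_rev, normalize = FALSE)$raw
  expect_identical(unname(fwd), unname(-rev))
})

test_that("delta ranks telescope: triangle rows sum to zero", {
  set.seed(11)
  gem <- tiny_gem(12, 5, seed = 12, with_ties = TRUE)
  for (rep in 1:100) {
    tri <- sample(rownames(gem), 3)
    net <- tiny_net(tri, tri[c(2, 3, 1)])  # (a,b), (b,c), (c,a)
    raw <- build_drm(gem, net, normalize = FALSE)$raw
    expect_identical(unname(colSums(raw)), rep(0, ncol(gem)))
  }
})

test_that("raw delta ranks are bounded by m - 1, attained for a unique max-min edge", {
  gem <- tiny_gem(10, 4, seed = 13, with_ties = TRUE)
  net <- tiny_net(paste0("g", 1:5), paste0("g", 6:10))
  raw <- build_drm(gem, net, normalize = FALSE)$raw
  expect_lte(max(abs(raw)), nrow(gem) - 1)

  # cell with unique extremes joined by an edge attains the bound
  gem2 <- cbind(c1 = c(10, 5, 4, 3, 1))
  rownames(gem2) <- paste0("g", 1:5)
  raw2 <- build_drm(gem2, tiny_net("g1", "g5"), normalize = FALSE)$raw
  expect_identical(unname(raw2[1, 1]), 4)
})

test_that("raw DRM is bitwise invariant to strictly increasing per-cell transforms", {
  sim <- simulate_gem(n_types = 2, cells_per_type = 6, n_genes = 40,
                      n_edges = 50, n_marker_edges_per_type = 4, seed = 21)
  gem <- sim$expression
  base <- build_drm(gem, sim$network, normalize = FALSE)$raw
  distortions <- list(
    apply_monotone_distortion(gem, "log1p"),
    apply_monotone_distortion(gem, "affine", list(scale = 3, shift = 7)),
    apply_monotone_distortion(gem, "power", list(exponent = 0.5)),
    apply_monotone_distortion(gem, "affine",
                              list(scale = runif(ncol(gem), 0.5, 5),
                                   shift = runif(ncol(gem), 0, 10)),
                              per_cell = TRUE)
  )
  for (d in distortions) {
    expect_identical(build_drm(d, sim$network, normalize = FALSE)$raw, base)
  }
})

test_that("DRM construction matches a direct brute-force implementation", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(3:6, 1); n <- sample(1:4, 1); l <- sample(1:6, 1)
    gem <- tiny_gem(m, n, seed = seed + 100, with_ties = seed %% 2 == 0)
    pairs <- t(combn(rownames(gem), 2))
    pick <- pairs[sample(nrow(pairs), min(l, nrow(pairs))), , drop = FALSE]
    net <- tiny_net(pick[, 1], pick[, 2])
    got <- build_drm(gem, net, normalize = FALSE)$raw
    want <- bf_drm_raw(gem, net$gene_a, net$gene_b)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the full build is deterministic and validates its inputs", {
  gem <- tiny_gem(6, 4, seed = 30)
  net <- tiny_net(c("g1", "g2", "g3", "g4"), c("g2", "g3", "g4", "g5"))
  a <- build_drm(gem, net)
  b <- build_drm(gem, net)
  expect_identical(a$raw, b$raw)
  expect_identical(a$normalized, b$normalized)
  expect_identical(dim(a), c(4L, 4L))
  expect_lte(nrow(a$raw), 4L)

  # normalized columns: mean ~ 0, sample sd ~ 1
  expect_lt(max(abs(colMeans(a$normalized))), 1e-9)
  expect_lt(max(abs(apply(a$normalized, 2, sd) - 1)), 1e-9)

  off_net <- tiny_net("x1", "x2")
  expect_error(build_drm(gem, off_net), class = "drm_empty_network_error")
})

test_that("non-default tie methods are available but change tied blocks only", {
  gem <- cbind(c1 = c(0, 0, 2, 5), c2 = c(1, 2, 3, 4))
  rownames(gem) <- paste0("g", 1:4)
  r_min <- rank_transform(gem, ties_method = "min")
  expect_identical(unname(r_min[, "c1"]), c(1, 1, 3, 4))
  expect_identical(unname(r_min[, "c2"]), unname(rank_transform(gem)[, "c2"]))
})
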