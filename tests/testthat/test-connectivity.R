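test_that("region averaging is the plain voxel mean", {
  cfg <- tiny_config(rs_n_timepoints = 30)
  atl <- tiny_atlas(cfg)
  d <- c(atl$grid$shape, 30L)
  arr <- array(rnorm(prod(d)), dim = d)
  bold <- bold_series(arr, atl$grid, 1)
  ts <- average_regions(bold, atl)
  # brute force: loop over regions and timepoints
  for (r in atl$region_table$region_id) {
    sel <- atl$labels == r
    manual <- vapply(seq_len(30), function(t) mean(arr[, , , t][sel]),
                     numeric(1))
    expect_equal(unname(ts[as.character(r), ]), manual, tolerance = 1e-12)
  }
  # two voxels at 0 and 2 average to 1
  arr2 <- array(0, dim = c(2, 1, 1, 4))
  arr2[2, 1, 1, ] <- 2
  lab <- array(1L, dim = c(2, 1, 1))
  atl2 <- atlas(lab, data.frame(region_id = 1, name = "r", macro_region = "m"))
  ts2 <- average_regions(bold_series(arr2, atl2$grid, 1), atl2)
  expect_equal(unname(ts2[1, ]), rep(1, 4))
})

test_that("Pearson matrices are symmetric, unit-diagonal and formula-exact", {
  set.seed(5)
  ts <- matrix(rnorm(10 * 40), 10, 40)
  rownames(ts) <- 1:10
  cm <- pearson_matrix(ts)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), rep(1, 10), ignore_attr = TRUE)
  expect_true(all(abs(cm$r) <= 1))
  expect_equal(cm$n_pairs, 45)
  for (i in 1:5) {
    a <- sample(10, 1); b <- sample(10, 1)
    expect_equal(cm$r[a, b], oracle_pearson(ts[a, ], ts[b, ]),
                 tolerance = 1e-10)
  }
  # a series with itself and with its negation
  two <- rbind(ts[1, ], -ts[1, ])
  cm2 <- pearson_matrix(two)
  expect_equal(cm2$r[1, 2], -1)
  # zero-variance regions are flagged and excluded
  ts[3, ] <- 5
  cm3 <- pearson_matrix(ts)
  expect_true("3" %in% cm3$flagged)
  expect_true(all(is.na(cm3$r[3, -3])))
  expect_equal(cm3$n_pairs, 36)
})

test_that("the full-scale atlas yields 14196 region pairs", {
  set.seed(6)
  ts <- matrix(rnorm(169 * 20), 169, 20)
  rownames(ts) <- 1:169
  expect_equal(pearson_matrix(ts)$n_pairs, 14196)
})

test_that("Fisher z is the closed-form atanh with clipping at the poles", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_z(r)
  expect_true(all(diff(z) > 0))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-9)
  clipped <- fisher_z(c(0.2, 1))
  expect_equal(attr(clipped, "clipped"), 2L)
  expect_true(is.finite(clipped[2]))
  expect_error(fisher_z(1.5), "<= 1")
})

test_that("group Z matches the t-then-quantile construction edge by edge", {
  set.seed(9)
  mats <- lapply(1:8, function(i) {
    m <- matrix(rnorm(36, sd = 0.3), 6, 6)
    m <- (m + t(m)) / 2; diag(m) <- NA
    m
  })
  gz <- group_z(mats)
  for (k in 1:10) {
    i <- sample(6, 1); j <- sample(6, 1)
    if (i == j) next
    vals <- vapply(mats, function(m) m[i, j], numeric(1))
    tt <- mean(vals) / (sd(vals) / sqrt(8))
    zo <- sign(tt) * qnorm(1 - 2 * pt(-abs(tt), df = 7) / 2)
    expect_equal(gz$Z[i, j], zo, tolerance = 1e-10)
  }
  # all-zero edges give Z = 0; identical nonzero edges cap and flag
  z0 <- lapply(1:4, function(i) matrix(0, 3, 3))
  expect_equal(group_z(z0)$Z[1, 2], 0)
  z1 <- lapply(1:4, function(i) matrix(0.7, 3, 3))
  g1 <- group_z(z1)
  expect_equal(g1$Z[1, 2], g1$z_cap)
  expect_gt(nrow(g1$capped), 0)
  # raw-t mode returns the t statistic itself
  gt <- group_z(mats, method = "raw_t")
  i <- 2; j <- 5
  vals <- vapply(mats, function(m) m[i, j], numeric(1))
  expect_equal(gt$Z[i, j], mean(vals) / (sd(vals) / sqrt(8)), tolerance = 1e-10)
})

test_that("thresholding produces a clean symmetric adjacency", {
  Z <- matrix(c(NA, 3, -1, 3, NA, -2.5, -1, -2.5, NA), 3, 3)
  A <- threshold_z(Z, 2.3)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_equal(A[1, 2], 1)
  expect_equal(A[2, 3], 1)  # negative edges count by magnitude
  expect_equal(A[1, 3], 0)
  expect_true(all(threshold_z(matrix(1, 4, 4), 2.3) == 0))
  A0 <- threshold_z(matrix(0.5, 4, 4), 0)
  expect_equal(sum(A0), 12)  # complete graph minus diagonal
  # suprathreshold edge count decreases with the cutoff
  set.seed(10)
  M <- matrix(rnorm(100, sd = 2), 10, 10); M <- (M + t(M)) / 2
  counts <- vapply(c(0, 1, 2.3, 4), function(cc) sum(threshold_z(M, cc)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mutual-kNN clustering separates well-separated blocks", {
  # clean two-block profile matrix: exactly 2 clusters at k = 3
  Z <- block_z_matrix(sizes = c(4, 4))
  cl <- knn_cluster(Z, k = 3)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[1] == cl[5])
  # identical rows collapse to one cluster
  same <- matrix(1, 5, 5); diag(same) <- NA
  expect_equal(length(unique(knn_cluster(same, k = 2))), 1)
  # k = N - 1 connects everything
  set.seed(11)
  R <- matrix(rnorm(49), 7, 7); R <- (R + t(R)) / 2; diag(R) <- NA
  expect_equal(length(unique(knn_cluster(R, k = 6))), 1)
  expect_error(knn_cluster(R, k = 7), "'k' must be")
})

test_that("planted communities are recovered from group resting-state data", {
  cfg <- sim_config(rs_n_communities = 2, rs_n_partners = 0)
  atl <- make_toy_atlas(cfg)
  pcfg <- pipeline_config()
  truth <- simulate_resting_state(atl, cfg, seed = 1)$truth
  nonhub <- which(!is.na(truth$community))
  hits <- 0
  for (s in 1:5) {
    conns <- lapply(1:6, function(i)
      run_rsfc_subject(simulate_resting_state(atl, cfg, seed = 100 * s + i)$ts,
                       pcfg))
    gz <- group_z(lapply(conns, `[[`, "z"))
    cl <- knn_cluster(gz$Z[nonhub, nonhub], k = 5)
    ok <- length(unique(cl)) == 2 &&
      length(unique(cl[truth$community[nonhub] == 1])) == 1 &&
      length(unique(cl[truth$community[nonhub] == 2])) == 1
    hits <- hits + ok
  }
  expect_gte(hits, 4)
})
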