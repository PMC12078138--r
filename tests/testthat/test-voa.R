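# small helper: wrap a voxel-by-time matrix as a bold_series on a 1-voxel-thick grid
mat_bold <- function(mat, tr = 6) {
  d <- c(nrow(mat), 1L, 1L)
  bold_series(array(mat, dim = c(d, ncol(mat))), volume_grid(d), tr)
}

test_that("percent change is exact simple arithmetic per voxel", {
  ws <- window_spec(c(0, 3), c(3, 6))
  # constant series: 0% everywhere
  pc <- percent_change(mat_bold(matrix(7, 2, 6)), ws)
  expect_true(all(pc$pc == 0))
  # baseline mean 100, scan value 104: +4%
  s <- matrix(c(100, 100, 100, 104, 99, 102), 1, 6)
  pc <- percent_change(mat_bold(s), ws)
  expect_equal(as.vector(pc$pc), c(0, 0, 0, 4, -1, 2))
  # nonpositive baseline excluded and counted
  s2 <- rbind(s, matrix(0, 1, 6))
  pc2 <- percent_change(mat_bold(s2), ws)
  expect_false(pc2$mask[2, 1, 1])
  expect_equal(pc2$qc$n_nonpositive_baseline, 1)
})

test_that("the signal floor keeps exactly the voxels that ever exceed it", {
  ws <- window_spec(c(0, 3), c(3, 6))
  mk <- function(peak) c(100, 100, 100, 100 + peak, 100, 100)
  s <- rbind(mk(0.9), mk(1.0), mk(-1.4), mk(0.2))
  pc <- percent_change(mat_bold(s), ws)
  inc <- apply_signal_floor(pc, 1.0)
  expect_equal(as.vector(inc), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(apply_signal_floor(pc, 0)))
  expect_error(apply_signal_floor(pc, -1), ">= 0")
})

test_that("the floor watches the whole post-injection period, not only the window", {
  ws <- window_spec(c(0, 3), c(6, 9))
  # excursion at scan 4 (between windows), flat inside the test window
  s <- matrix(c(100, 100, 100, 103, 100, 100, 100, 100, 100), 1, 9)
  pc <- percent_change(mat_bold(s), ws)
  expect_true(as.vector(apply_signal_floor(pc, 1.0)))
})

test_that("voxelwise t statistics match the closed form", {
  ws <- window_spec(c(0, 3), c(3, 6))
  base <- c(100, 100, 100)
  mk <- function(stim) matrix(c(base, 100 * (1 + stim / 100)), 1, 6)
  run <- function(stim) {
    pc <- percent_change(mat_bold(mk(stim)), ws)
    voxel_ttest(pc, array(TRUE, dim = c(1, 1, 1)))
  }
  # symmetric samples around zero: t = 0, p = 1
  t0 <- run(c(-1, 0, 1))
  expect_equal(t0$t[1, 1, 1], 0)
  expect_equal(t0$p[1, 1, 1], 1)
  # (1, 2, 3): t = mean / (sd / sqrt(3)) = 2 sqrt(3)
  t1 <- run(c(1, 2, 3))
  expect_equal(t1$t[1, 1, 1], 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(t1$p[1, 1, 1], 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  # independent check through the stock t-test
  expect_equal(t1$p[1, 1, 1], t.test(c(1, 2, 3))$p.value, tolerance = 1e-12)
  # constant nonzero stimulation values: zero-variance branch, flagged
  t2 <- run(c(2, 2, 2))
  expect_equal(t2$p[1, 1, 1], 0)
  expect_equal(t2$qc$n_zero_variance, 1)
  # all-zero change: p = 1
  t3 <- run(c(0, 0, 0))
  expect_equal(t3$p[1, 1, 1], 1)
})

test_that("the step-up FDR filter matches brute-force enumeration", {
  f <- fdr_filter(c(0.01, 0.02, 0.04, 0.9), q = 0.05)
  expect_equal(f$pass, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f$cutoff_rank, 2L)
  expect_false(any(fdr_filter(rep(1, 10), q = 0.05)$pass))
  expect_equal(fdr_filter(numeric(0), q = 0.05)$V, 0L)
  # default q is 0.05
  expect_equal(formals(fdr_filter)$q, 0.05)
  set.seed(13)
  for (i in 1:200) {
    V <- sample(200, 1)
    p <- switch(sample(3, 1), runif(V), rbeta(V, 0.3, 3),
                round(runif(V), 2))  # include heavy ties
    q <- sample(c(0.01, 0.05, 0.2), 1)
    f <- fdr_filter(p, q)
    expect_identical(f$pass, brute_force_stepup(p, q))
    # pass set is a subset of the uncorrected p <= q set
    expect_true(all(p[f$pass] <= q))
    # agreement with the stock BH adjustment at c(V) = 1
    expect_identical(f$pass, unname(p.adjust(p, "BH") <= q))
  }
  # the arbitrary-dependence constant c(V) tightens the filter
  p <- c(0.01, 0.02, 0.04, 0.9)
  cV <- sum(1 / (1:4))
  expect_identical(fdr_filter(p, 0.05, c_V = cV)$pass,
                   brute_force_stepup(p, 0.05, c_V = cV))
})

test_that("VoA counting respects region boundaries and signs", {
  cfg <- tiny_config()
  atl <- tiny_atlas(cfg)
  d <- atl$grid$shape
  tests <- list(p = array(1, dim = d), mean_pc = array(0, dim = d),
                included = array(TRUE, dim = d))
  tests$significant <- array(FALSE, dim = d)
  tests$sign <- array(0L, dim = d)
  class(tests) <- "voxel_tests"
  # nothing significant: all zeros
  t0 <- count_voa(tests, atl)
  expect_true(all(t0$positive_voa == 0) && all(t0$negative_voa == 0))
  # every voxel of region 1 significant-positive: fraction 1
  r1 <- atl$labels == 1L
  tests$significant[r1] <- TRUE
  tests$sign[r1] <- 1L
  t1 <- count_voa(tests, atl)
  expect_equal(t1$positive_voa[1], t1$region_n_voxels[1])
  expect_equal(t1$positive_fraction[1], 1)
  expect_equal(t1$negative_voa[1], 0)
  # positive and negative are disjoint and bounded by region size
  tests$sign[which(r1)[1:5]] <- -1L
  t2 <- count_voa(tests, atl)
  expect_true(all(t2$positive_voa + t2$negative_voa <= t2$region_n_voxels))
  expect_equal(t2$negative_voa[1], 5)
})

test_that("significant implies included, and sign follows the mean change", {
  cfg <- tiny_config(seed = 17)
  atl <- tiny_atlas(cfg)
  ses <- simulate_phmri_session(atl, 3, cfg, seed = 17)
  res <- run_voa_subject(ses$bold, atl,
                         pipeline_config(baseline = cfg$baseline,
                                         stimulation = cfg$stimulation))
  expect_true(all(res$tests$included[res$tests$significant]))
  sig <- res$tests$significant
  expect_true(all((res$tests$sign[sig] > 0) == (res$tests$mean_pc[sig] > 0)))
  expect_true(all(res$tests$sign[!sig] == 0L))
})

test_that("composite maps average subject contributions through inverse transforms", {
  set.seed(23)
  grid <- volume_grid(c(8, 6, 4))
  a <- array(rnorm(8 * 6 * 4), dim = c(8, 6, 4))
  b <- array(rnorm(8 * 6 * 4), dim = c(8, 6, 4))
  id <- affine_transform(diag(4))
  # single subject, identity: exact copy
  expect_equal(as.vector(composite_map(list(a), list(id), grid)),
               as.vector(a), tolerance = 1e-12)
  # two subjects, identity: exact voxelwise mean
  cm <- composite_map(list(a, b), list(id, id), grid)
  expect_equal(as.vector(cm), as.vector((a + b) / 2), tolerance = 1e-12)
  # integer translation: composite equals the index-shifted map
  shift <- affine_transform(matrix(c(1, 0, 0, 2,
                                     0, 1, 0, 0,
                                     0, 0, 1, 0,
                                     0, 0, 0, 1), 4, 4, byrow = TRUE))
  cs <- composite_map(list(a), list(shift), grid)
  # subject voxel v maps to composite voxel v + 2 on x
  expect_equal(cs[3:8, , ], a[1:6, , ], tolerance = 1e-12)
  # uncovered voxels are missing and counted
  expect_true(all(is.na(cs[1:2, , ])))
  expect_equal(attr(cs, "qc")$n_uncovered, 2 * 6 * 4)
})

test_that("region time courses pool regions then average across subjects", {
  cfg <- tiny_config()
  atl <- tiny_atlas(cfg)
  ws <- window_spec(cfg$baseline, cfg$stimulation)
  flat <- function(pcval) {
    d <- c(atl$grid$shape, cfg$n_acquisitions)
    arr <- array(100, dim = d)
    arr[, , , window_index(cfg$stimulation)] <- 100 * (1 + pcval / 100)
    percent_change(bold_series(arr, atl$grid, 6), ws)
  }
  tc <- region_timecourse(list(flat(2), flat(2)), atl, region_ids = c(1, 2))
  stim <- window_index(cfg$stimulation)
  expect_equal(tc$mean[stim], rep(2, length(stim)))
  expect_equal(tc$se[stim], rep(0, length(stim)))
  tc2 <- region_timecourse(list(flat(1), flat(3)), atl, region_ids = 1)
  expect_equal(tc2$mean[stim], rep(2, length(stim)))
  expect_equal(tc2$se[stim], rep(1, length(stim)))
  expect_error(region_timecourse(list(flat(1), flat(3)), atl, integer(0)),
               "nonempty")
  # a simulated ramp crosses the 1% line after the planted onset
  ses <- lapply(1:3, function(i) simulate_phmri_session(atl, 3, cfg, seed = i))
  pcs <- lapply(ses, function(s) percent_change(s$bold, ws))
  tr <- region_timecourse(pcs, atl, region_ids = atl$region_table$region_id)
  first_cross <- min(which(tr$mean > 1))
  expect_gt(first_cross, ses[[1]]$truth$onset_scan)
  expect_lt(first_cross, cfg$stimulation[2])
})
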