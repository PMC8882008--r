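test_that("frame schedules reject malformed frames", {
  expect_error(frame_schedule(c(0, 10), c(10, -5)), "positive")
  expect_error(frame_schedule(c(0, 20), c(10, 10)), "contiguous")
  expect_error(frame_schedule(c(10, 0), c(10, 10)), "increasing")
  expect_error(tac(default_frame_schedule(), 1:5), "match")
})

test_that("cumulative TAC integral matches constants and quadrature", {
  sched <- default_frame_schedule()
  const <- tac(sched, rep(1, 30))
  ints <- integrate_tac(const)
  # integral at the last mid-time of a constant-1 curve ~ the mid-time
  expect_equal(ints[30], sched$mid_min[30], tolerance = 0.01)
  expect_equal(integrate_tac(tac(sched, rep(0, 30))), rep(0, 30))

  amp <- 50; l1 <- 0.04; l2 <- 0.6
  ref <- generate_reference_tac(sched, amp, l1, l2)
  f <- function(t) amp * (exp(-l1 * t) - exp(-l2 * t))
  ints <- integrate_tac(ref)
  oracle <- sapply(sched$mid_min,
                   function(T) integrate(f, 0, T, rel.tol = 1e-10)$value)
  # sub-minute frames hold a tiny fraction of the integral; relative
  # accuracy there is curvature-limited given frame-binned data, so they
  # get an absolute bound instead
  late <- sched$mid_min >= 1
  expect_lt(max(abs(ints[late] - oracle[late]) / oracle[late]), 0.01)
  expect_lt(max(abs(ints[!late] - oracle[!late])), 0.001 * oracle[30])
})

test_that("MRTM recovers SRTM parameters from noiseless curves", {
  ref <- generate_reference_tac()
  tgt <- generate_target_tac(ref, R1 = 1, k2 = 0.15, DVR = 1.5)
  fit <- fit_mrtm(tgt, ref, t_star = 20)
  expect_equal(fit$DVR, 1.5, tolerance = 0.02)
  expect_equal(fit$k2prime, 0.15, tolerance = 0.05)

  zero <- tac(ref$schedule, rep(0, 30))
  expect_error(fit_mrtm(zero, ref), "degenerate")
})

test_that("MRTM DVR has small median bias under 1% frame noise", {
  ref <- generate_reference_tac()
  noiseless <- generate_target_tac(ref, R1 = 0.9, k2 = 0.15, DVR = 1.5)
  sd1 <- 0.01 * max(noiseless$activity)
  set.seed(77)
  dvrs <- replicate(100, {
    noisy <- tac(ref$schedule, noiseless$activity + rnorm(30, sd = sd1))
    fit_mrtm(noisy, ref)$DVR
  })
  expect_lt(abs(median(dvrs) / 1.5 - 1), 0.05)
})

test_that("MRTM2 is exact for self-reference and recovers a DVR grid", {
  ref <- generate_reference_tac()
  self <- fit_mrtm2(ref, ref, k2prime = 0.5, t_star = 20)
  expect_equal(self$DVR, 1.0, tolerance = 1e-6)

  k2 <- 0.15
  for (dvr in seq(1.0, 2.4, by = 0.2)) {
    tgt <- generate_target_tac(ref, R1 = 1, k2 = k2, DVR = dvr)
    fit <- fit_mrtm2(tgt, ref, k2prime = k2, t_star = 20)
    expect_equal(fit$DVR, dvr, tolerance = 0.02)
  }
  expect_error(fit_mrtm2(ref, ref, k2prime = 0), "positive")
  expect_error(fit_mrtm2(ref, ref, k2prime = -0.1), "positive")
})

test_that("DVR estimates are invariant to joint rescaling of both TACs", {
  ref <- generate_reference_tac()
  tgt <- generate_target_tac(ref, R1 = 0.8, k2 = 0.12, DVR = 1.8)
  scale_tac <- function(x, f) tac(x$schedule, x$activity * f)
  f1 <- fit_mrtm2(tgt, ref, k2prime = 0.15)
  f2 <- fit_mrtm2(scale_tac(tgt, 37.5), scale_tac(ref, 37.5),
                  k2prime = 0.15)
  expect_equal(f1$DVR, f2$DVR, tolerance = 1e-10)
  g1 <- fit_mrtm(tgt, ref)
  g2 <- fit_mrtm(scale_tac(tgt, 0.004), scale_tac(ref, 0.004))
  expect_equal(g1$DVR, g2$DVR, tolerance = 1e-10)
})

test_that("MRTM2 converges to the two-term fit as k2prime grows", {
  ref <- generate_reference_tac()
  tgt <- generate_target_tac(ref, R1 = 0.9, k2 = 0.15, DVR = 1.5)
  keep <- ref$schedule$mid_min >= 20
  X <- cbind(integrate_tac(ref)[keep], integrate_tac(tgt)[keep])
  beta <- qr.solve(X, tgt$activity[keep])
  limit_dvr <- -beta[1] / beta[2]
  fit <- fit_mrtm2(tgt, ref, k2prime = 1e8)
  expect_equal(fit$DVR, limit_dvr, tolerance = 1e-6)
})

test_that("voxel-wise DVR mapping recovers planted kinetics", {
  sched <- default_frame_schedule()
  ref <- generate_reference_tac(sched)
  dims <- c(6, 6, 6)
  true_dvr <- array(sample(c(1.0, 1.5), prod(dims), replace = TRUE), dims)
  curves <- list(`1` = generate_target_tac(ref, R1 = 1, k2 = 0.15, DVR = 1),
                 `1.5` = generate_target_tac(ref, R1 = 1, k2 = 0.15,
                                             DVR = 1.5))
  dyn <- array(0, c(dims, 30))
  for (v in which(true_dvr == 1.0))
    dyn[arrayInd(v, dims)[1], arrayInd(v, dims)[2], arrayInd(v, dims)[3], ] <-
      curves[["1"]]$activity
  for (v in which(true_dvr == 1.5))
    dyn[arrayInd(v, dims)[1], arrayInd(v, dims)[2], arrayInd(v, dims)[3], ] <-
      curves[["1.5"]]$activity
  ref_arr <- array(0, dims); ref_arr[, , 1] <- 1
  hb_arr <- array(0, dims); hb_arr[, , 6] <- as.numeric(true_dvr[, , 6] == 1.5)
  # make the reference-mask voxels actually hold the reference curve
  for (v in which(ref_arr == 1))
    dyn[arrayInd(v, dims)[1], arrayInd(v, dims)[2], arrayInd(v, dims)[3], ] <-
      ref$activity
  true_dvr[, , 1] <- NA  # excluded from the check below
  dvr_map <- dvr_map_from_dynamic(dyn, parametric_map(ref_arr),
                                  parametric_map(hb_arr), sched)
  err <- abs(dvr_map$values - true_dvr) / true_dvr
  expect_lt(max(err, na.rm = TRUE), 0.03)
  expect_true(is.finite(attr(dvr_map, "k2prime")))

  # identical homogeneous reference and target regions: degenerate fits
  flat <- array(rep(ref$activity, each = prod(dims)), c(dims, 30))
  expect_error(
    dvr_map_from_dynamic(flat, parametric_map(ref_arr),
                         parametric_map(ref_arr), sched),
    "k2prime|degenerate")
})

test_that("voxel-wise fitting stays within the performance budget", {
  sched <- default_frame_schedule()
  ref <- generate_reference_tac(sched)
  dims <- c(22, 22, 22)  # ~10^4 voxels
  base <- generate_target_tac(ref, R1 = 1, k2 = 0.15, DVR = 1.4)
  set.seed(5)
  dyn <- array(rep(base$activity, each = prod(dims)) *
                 (1 + 0.01 * rnorm(prod(dims) * 30)), c(dims, 30))
  ref_arr <- array(0, dims); ref_arr[1:2, 1, 1] <- 1
  dyn[1, 1, 1, ] <- ref$activity
  dyn[2, 1, 1, ] <- ref$activity
  hb_arr <- array(0, dims); hb_arr[10:12, 10:12, 10:12] <- 1
  elapsed <- system.time(
    dvr_map_from_dynamic(dyn, parametric_map(ref_arr),
                         parametric_map(hb_arr), sched))["elapsed"]
  expect_lt(elapsed, 60)
})

test_that("amyloid status respects the DVR cut-offs, boundaries included", {
  expect_equal(summarize_cortical_amyloid(1.41)$status, "high")
  expect_equal(summarize_cortical_amyloid(1.08)$status, "low")
  expect_equal(summarize_cortical_amyloid(1.20)$status, "high")
  expect_equal(summarize_cortical_amyloid(1.15)$status, "indeterminate")
  expect_error(summarize_cortical_amyloid(1.2, low = 1.3, high = 1.2),
               "below")
})

test_that("cohort amyloid percentages are reported to one decimal", {
  counts <- mci_cohort_reference()$amyloid_counts
  dvr <- c(rep(1.00, 6), rep(1.30, 24), rep(1.15, 47 - 6 - 24),
           rep(1.00, 6), rep(1.30, 7), rep(1.15, 37 - 6 - 7))
  grp <- c(rep("mci", 47), rep("comparison", 37))
  tab <- summarize_cortical_amyloid(dvr, group = grp)$table
  mci <- tab[tab$group == "mci", ]
  hc <- tab[tab$group == "comparison", ]
  expect_equal(mci$pct_high, 51.1)
  expect_equal(mci$pct_low, 12.8)
  expect_equal(hc$pct_high, 18.9)
  expect_equal(hc$pct_low, 16.2)
  expect_equal(mci$n_high, counts$n_high[counts$group == "mci"])

  # map + mask form excludes NaN voxels
  arr <- array(1.5, c(3, 3, 3)); arr[1] <- NaN
  s <- summarize_cortical_amyloid(parametric_map(arr),
                                  parametric_map(array(1, c(3, 3, 3))))
  expect_equal(s$mean_cortical_dvr, 1.5)
  expect_equal(s$n_excluded_voxels, 1L)
})
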