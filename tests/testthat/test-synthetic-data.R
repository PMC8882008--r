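test_that("generators are seed-deterministic", {
  cfg <- synthetic_pls_config(n_subjects = 10, grid_dims = c(5, 5, 5),
                              seed = 42)
  d1 <- generate_pls_dataset(cfg)
  d2 <- generate_pls_dataset(cfg)
  expect_identical(d1$behaviour, d2$behaviour)
  expect_identical(d1$maps[[3]]$values, d2$maps[[3]]$values)

  ref <- generate_reference_tac()
  t1 <- generate_target_tac(ref, DVR = 1.4, noise_sd = 2, seed = 9)
  t2 <- generate_target_tac(ref, DVR = 1.4, noise_sd = 2, seed = 9)
  expect_identical(t1$activity, t2$activity)

  spec <- mci_cohort_reference()$spec
  expect_identical(generate_cohort_scores(spec, seed = 3),
                   generate_cohort_scores(spec, seed = 3))
})

test_that("config validation rejects ill-posed scenarios", {
  expect_error(synthetic_pls_config(n_subjects = 2), "at least 3")
  expect_error(synthetic_pls_config(grid_dims = c(0, 5, 5)), "positive")
  expect_error(synthetic_pls_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_pls_config(signal_region = 1e6),
               "outside the grid")
  expect_error(
    synthetic_pls_config(behaviour_loadings = c(a = 0, b = 0),
                         effect_size = 1),
    "not all be zero")
})

test_that("reference TAC matches the default schedule and a quadrature oracle", {
  sched <- default_frame_schedule()
  expect_length(sched, 30L)
  expect_equal(sum(sched$duration), 90 * 60)

  amp <- 100; l1 <- 0.03; l2 <- 0.5
  ref <- generate_reference_tac(sched, amp, l1, l2)
  expect_length(ref$activity, 30L)
  expect_true(all(ref$activity >= 0))
  # first frame starts at injection: near zero relative to the peak
  expect_lt(ref$activity[1], max(ref$activity) / 10)
  # frame means against adaptive quadrature of the bi-exponential
  f <- function(t) amp * (exp(-l1 * t) - exp(-l2 * t))
  for (k in c(1, 5, 12, 30)) {
    a <- sched$start[k] / 60; b <- (sched$start[k] + sched$duration[k]) / 60
    oracle <- integrate(f, a, b, rel.tol = 1e-10)$value / (b - a)
    expect_equal(ref$activity[k], oracle, tolerance = 0.005)
  }
  expect_error(generate_reference_tac(sched, lambda1 = 0.5, lambda2 = 0.3),
               "lambda2 > lambda1")
})

test_that("SRTM target curve collapses to the reference when R1 = 1, DVR = 1", {
  ref <- generate_reference_tac()
  tgt <- generate_target_tac(ref, R1 = 1, k2 = 0.15, DVR = 1)
  expect_equal(tgt$activity, ref$activity, tolerance = 1e-8)
})

test_that("late-frame target/reference ratio increases with DVR", {
  ref <- generate_reference_tac()
  late <- 25:30
  ratios <- sapply(seq(1.0, 2.4, by = 0.2), function(dvr) {
    tgt <- generate_target_tac(ref, R1 = 1, k2 = 0.15, DVR = dvr)
    mean(tgt$activity[late] / ref$activity[late])
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("cohort generator respects group sizes and specified moments", {
  spec <- cohort_spec(list(
    g1 = list(n = 10000, mean = c(a = 5, b = -2), sd = c(a = 2, b = 1)),
    g2 = list(n = 10000, mean = c(a = 7, b = 0), sd = c(a = 2, b = 3))))
  tab <- generate_cohort_scores(spec, seed = 11)
  expect_equal(unname(table(tab$group)[c("g1", "g2")]),
               c(10000L, 10000L), ignore_attr = TRUE)
  for (g in c("g1", "g2")) for (v in c("a", "b")) {
    x <- tab[tab$group == g, v]
    se <- spec$groups[[g]]$sd[[v]] / sqrt(spec$groups[[g]]$n)
    expect_lt(abs(mean(x) - spec$groups[[g]]$mean[[v]]), 3 * se)
  }
  expect_error(cohort_spec(list(g = list(n = 1, mean = c(a = 0),
                                         sd = c(a = 1)))), "n >= 2")
})

test_that("planted latent variable dominates as noise vanishes", {
  cfg <- synthetic_pls_config(n_subjects = 100, grid_dims = c(6, 6, 6),
                              noise_sd = 0.01, effect_size = 1.5, seed = 5)
  d <- generate_pls_dataset(cfg)
  X <- t(vapply(d$maps, function(m) as.numeric(m$values),
                numeric(prod(cfg$grid_dims))))
  fit <- fit_pls(X, d$behaviour)
  expect_gt(fit$covariance_explained[1], 95)
})

test_that("null-data permutation p-values are approximately uniform", {
  # effect 0: LV1 p over replicate datasets should be uniform
  n_rep <- 200
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_pls_config(n_subjects = 50, grid_dims = c(3, 3, 3),
                                effect_size = 0, seed = 1000 + r)
    d <- generate_pls_dataset(cfg)
    X <- t(vapply(d$maps, function(m) as.numeric(m$values), numeric(27)))
    pvals[r] <- permutation_test(X, d$behaviour, n_perm = 100,
                                 seed = r)$p_values[1]
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fitted voxel saliences recover the planted pattern", {
  # scaled-down recovery sweep; the full 100-replicate version runs in the
  # acceptance suite
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_pls_config(n_subjects = 80, grid_dims = c(8, 8, 5),
                                signal_region = 1:200, effect_size = 1.5,
                                seed = 200 + r)
    d <- generate_pls_dataset(cfg)
    X <- t(vapply(d$maps, function(m) as.numeric(m$values), numeric(320)))
    fit <- fit_pls(X, d$behaviour)
    cosine <- abs(sum(fit$voxel_saliences[, 1] *
                        d$ground_truth$true_voxel_salience))
    if (cosine > 0.9) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
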