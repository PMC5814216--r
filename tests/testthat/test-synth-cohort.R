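test_that("cohort simulation is deterministic given the seed", {
  cfg <- cohort_config(n_patients = 4, seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
})

test_that("the default cohort has one record of every kind per patient", {
  fx <- default_cohort()
  co <- fx$cohort
  expect_length(co$imaging, 65)
  expect_equal(ncol(co$expression), 65)
  expect_equal(ncol(co$mutations), 65)
  expect_equal(ncol(co$cnv), 65)
  expect_equal(nrow(co$survival), 65)
  expect_length(co$truth$subtype_labels, 65)
  dims <- unique(lapply(co$imaging, function(im) dim(im$dwi_b0)))
  expect_length(dims, 1)
  # T1CE ROI nested inside the FLAIR ROI
  expect_true(all(vapply(co$imaging, function(im)
    all(im$t2flair_mask[im$t1ce_mask]), TRUE)))
})

test_that("a degenerate mixture assigns every patient to one profile", {
  pr <- default_profiles()
  pr[[1]]$prevalence <- 1; pr[[2]]$prevalence <- 0; pr[[3]]$prevalence <- 0
  co <- simulate_cohort(cohort_config(n_patients = 4, profiles = pr, seed = 2L))
  expect_true(all(co$truth$subtype_labels == pr[[1]]$name))
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(n_patients = 2), "n_patients")
  expect_error(cohort_config(voxel_spacing = c(1, 0, 5)), "voxel_spacing")
  expect_error(cohort_config(censoring_rate = 1), "censoring_rate")
  pr <- default_profiles(); pr[[1]]$prevalence <- 0.9
  expect_error(cohort_config(profiles = pr), "prevalences")
  pr2 <- default_profiles(); pr2[[2]]$marker_block <- pr2[[1]]$marker_block
  expect_error(cohort_config(profiles = pr2), "disjoint")
})

test_that("DWI pair inverts exactly without noise and is unbiased with noise", {
  adc <- array(runif(1000, 0.4e-3, 1.4e-3), c(10, 10, 10))
  p <- simulate_dwi_pair(adc, s0 = 1000, noise_sd = 0)
  expect_equal(compute_adc(p$b0, p$b1000), adc,
               tolerance = 1e-10, ignore_attr = TRUE)

  z <- simulate_dwi_pair(array(0, c(2, 2)), s0 = 500, noise_sd = 0)
  expect_equal(z$b0, array(500, c(2, 2)))
  expect_equal(z$b1000, array(500, c(2, 2)))
  expect_error(simulate_dwi_pair(array(-1, c(2, 2))), "non-negative")

  # Monte-Carlo: voxelwise estimates unbiased within 3 standard errors
  set.seed(8)
  truth <- array(1e-3, c(10, 10, 10))
  pn <- simulate_dwi_pair(truth, s0 = 1000, noise_sd = 5)
  est <- compute_adc(pn$b0, pn$b1000)
  bias <- mean(est) - 1e-3
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(bias), 3 * se)
})

test_that("DSC forward model is flat at zero amplitude and checks the window", {
  zero <- lapply(c(k_amp = 0, t0 = 10, alpha_g = 2, beta_g = 1.5), function(v)
    array(v, c(2, 2)))
  ser <- simulate_dsc_series(zero, dsc_pars(), noise_sd = 0, s0 = 100)
  expect_true(all(ser$data == 100))

  long <- lapply(c(k_amp = 10, t0 = 10, alpha_g = 2, beta_g = 20), function(v)
    array(v, c(1, 1)))
  expect_error(simulate_dsc_series(long, dsc_pars()), "too short")
})

test_that("leakage produces a non-returning tail that correction removes", {
  pars <- lapply(c(k_amp = 30, t0 = 10, alpha_g = 2, beta_g = 1.5), function(v)
    array(v, c(1, 1)))
  ref_pars <- lapply(c(k_amp = 15, t0 = 10, alpha_g = 2, beta_g = 1.6),
                     function(v) array(v, c(1, 1)))
  leaky <- simulate_dsc_series(pars, dsc_pars(), leakage_k2 = 0.05, noise_sd = 0)
  clean_ref <- simulate_dsc_series(ref_pars, dsc_pars(), noise_sd = 0)
  curve <- signal_to_relaxation(leaky)[, 1, 1]
  refc <- signal_to_relaxation(clean_ref)[, 1, 1]
  times <- leaky$times
  tail_idx <- (length(times) - 4):length(times)
  expect_gt(max(abs(curve[tail_idx])), 0.05 * max(curve))
  corrected <- correct_leakage(curve, refc, times)$corrected
  expect_lt(max(abs(corrected[tail_idx])), 0.05 * max(corrected))
})

test_that("expression marker blocks shift only their own subtype", {
  pr <- default_profiles(n_marker = 5)
  labels <- rep(vapply(pr, `[[`, "", "name"), each = 10)

  x <- simulate_expression(labels, pr, n_genes = 100, noise_sd = 1, seed = 3L)
  expect_equal(dim(x), c(100, 30))
  m1 <- pr[[1]]$marker_block
  in1 <- labels == pr[[1]]$name
  expect_gt(mean(x[m1, in1]) - mean(x[m1, !in1]), 1)

  pr2 <- default_profiles(n_marker = 2)
  lab2 <- rep(vapply(pr2, `[[`, "", "name"), each = 3)
  expect_equal(nrow(simulate_expression(lab2, pr2, n_genes = 10, seed = 1L)), 10)
  bad <- pr; bad[[2]]$marker_block <- bad[[1]]$marker_block
  expect_error(simulate_expression(labels, bad, n_genes = 100), "overlapping")
})

test_that("null expression separates no genes beyond chance", {
  pr <- default_profiles(n_marker = 5)
  for (p in seq_along(pr)) pr[[p]]$expression_delta <- 0
  labels <- rep(vapply(pr, `[[`, "", "name"), c(22, 21, 22))
  x <- simulate_expression(labels, pr, n_genes = 1000, noise_sd = 1, seed = 21L)
  g1 <- labels == pr[[1]]$name
  pv <- apply(x, 1, function(v)
    mannwhitney_test(v, which(g1), which(!g1))$p)
  expect_equal(mean(pv < 0.05), 0.05, tolerance = 0.02)
})

test_that("a large expression effect gives every marker gene p < 0.01", {
  pr <- default_profiles(n_marker = 10)
  for (p in seq_along(pr)) pr[[p]]$expression_delta <- 5
  labels <- rep(vapply(pr, `[[`, "", "name"), c(22, 21, 22))
  x <- simulate_expression(labels, pr, n_genes = 100, noise_sd = 1, seed = 4L)
  for (p in pr) {
    inp <- labels == p$name
    pv <- apply(x[p$marker_block, ], 1, function(v)
      mannwhitney_test(v, which(inp), which(!inp))$p)
    expect_true(all(pv < 0.01))
  }
})

test_that("survival times follow the configured exponential hazards", {
  pr <- default_profiles()
  pr[[1]]$hazard <- log(2) / 13.2
  labels <- rep(pr[[1]]$name, 10000)
  s <- simulate_survival(labels, pr, censoring_rate = 0, seed = 6L)
  expect_true(all(s$event))
  expect_equal(median(s$time), 13.2, tolerance = 0.05)
  expect_error(simulate_survival(labels, pr, censoring_rate = 1), "censoring")

  # censoring calibration: expected censored fraction
  s2 <- simulate_survival(labels, pr, censoring_rate = 0.3, seed = 6L)
  expect_equal(mean(!s2$event), 0.3, tolerance = 0.03)
})

test_that("a 3-fold hazard contrast is detectable at n = 65", {
  pr <- default_profiles()[1:2]
  pr[[1]]$prevalence <- 0.5; pr[[2]]$prevalence <- 0.5
  pr[[1]]$hazard <- log(2) / 6; pr[[2]]$hazard <- log(2) / 18
  labels <- rep(c(pr[[1]]$name, pr[[2]]$name), c(33, 32))
  hits <- vapply(1:100, function(r) {
    s <- simulate_survival(labels, pr, censoring_rate = 0, seed = 1000L + r)
    km_logrank(s)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
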