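test_that("ADC computation matches the per-voxel log-ratio", {
  eq <- compute_adc(matrix(1000, 2, 2), matrix(1000, 2, 2), b = 1000)
  expect_equal(as.numeric(eq), rep(0, 4))

  two <- compute_adc(array(1000, c(1, 1, 1)), array(1000 * exp(-2), c(1, 1, 1)),
                     b = 1000)
  expect_equal(as.numeric(two), 2e-3, tolerance = 1e-12)

  set.seed(1)
  s0 <- array(runif(1000, 500, 1500), c(10, 10, 10))
  s1 <- array(runif(1000, 100, 1400), c(10, 10, 10))
  adc <- compute_adc(s0, s1, b = 900)
  oracle <- pmax(log(s0 / s1) / 900, 0)
  expect_equal(as.numeric(adc), as.numeric(oracle), tolerance = 1e-12)
  expect_equal(attr(adc, "n_clamped"), sum(log(s0 / s1) < 0))

  # invariant: common scaling of both volumes cancels
  expect_equal(as.numeric(compute_adc(3.7 * s0, 3.7 * s1, b = 900)),
               as.numeric(adc), tolerance = 1e-12)

  expect_error(compute_adc(matrix(c(-1, 2), 1), matrix(c(1, 2), 1)),
               "non-positive signal.*1 voxel")
})

test_that("signal-to-relaxation conversion has zero baseline and closed form", {
  s <- dsc_series(matrix(200, 20, 3), tr = 1.72, te = 0.035,
                  baseline_window = 1:5)
  expect_equal(signal_to_relaxation(s), matrix(0, 20, 3))

  sig <- matrix(100, 20, 1)
  sig[10, 1] <- 100 * exp(-0.35)
  s2 <- dsc_series(sig, tr = 1.72, te = 0.035, baseline_window = 1:5)
  expect_equal(signal_to_relaxation(s2)[10, 1], 10, tolerance = 1e-12)

  # scale equivariance: multiplying the signal leaves the curve unchanged
  s3 <- dsc_series(5 * sig, tr = 1.72, te = 0.035, baseline_window = 1:5)
  expect_equal(signal_to_relaxation(s3), signal_to_relaxation(s2))

  bad <- dsc_series(matrix(1, 20, 1), tr = 1, te = 0.03, baseline_window = 1:5)
  bad$data[1:5, 1] <- -1
  expect_error(signal_to_relaxation(bad), "baseline")
})

test_that("gamma-variate fitting recovers noiseless parameters", {
  times <- seq(0, 25, by = 0.5)
  curve <- gamma_variate(times, 1, 0, 2, 1)
  for (m in c("nls", "loglin")) {
    ft <- fit_gamma_variate(curve, times, method = m)
    expect_true(ft$converged)
    expect_equal(c(ft$k_amp, ft$t0, ft$alpha_g, ft$beta_g), c(1, 0, 2, 1),
                 tolerance = 1e-6)
  }
  shifted <- gamma_variate(times, 4, 5, 3, 0.8)
  fs <- fit_gamma_variate(shifted, times)
  expect_equal(c(fs$k_amp, fs$t0, fs$alpha_g, fs$beta_g), c(4, 5, 3, 0.8),
               tolerance = 1e-6)
})

test_that("degenerate curves yield converged = FALSE, not an error", {
  expect_false(fit_gamma_variate(rep(0, 20))$converged)
  expect_false(fit_gamma_variate(rep(3, 20))$converged)
  expect_false(fit_gamma_variate(rnorm(20, 0, 1e-4) - 10)$converged)
})

test_that("fit is accurate under 1% peak noise", {
  times <- seq(0, 30, by = 0.6)
  truth <- c(k = 20, t0 = 8, a = 2, b = 1.5)
  clean <- gamma_variate(times, truth["k"], truth["t0"], truth["a"], truth["b"])
  peak <- max(clean)
  set.seed(42)
  err <- replicate(100, {
    ft <- fit_gamma_variate(clean + rnorm(length(times), 0, 0.01 * peak), times)
    abs(c(ft$k_amp, ft$t0, ft$alpha_g, ft$beta_g) - truth) / truth
  })
  expect_true(all(apply(err, 1, median) < 0.05))
})

test_that("leakage correction recovers the planted coefficient", {
  times <- seq(0, 84, by = 1.72)
  ref <- gamma_variate(times, 15, 10, 2, 1.6)
  ci <- cumsum(c(0, diff(times) * (ref[-1] + ref[-length(ref)]) / 2))

  no_leak <- 1.1 * ref
  r0 <- correct_leakage(no_leak, ref, times)
  expect_lt(abs(r0$k2), 1e-8)
  expect_equal(r0$corrected, no_leak, tolerance = 1e-10)

  leaky <- 0.9 * ref - 0.05 * ci
  r1 <- correct_leakage(leaky, ref, times)
  expect_equal(r1$k2, 0.05, tolerance = 1e-6)

  # tail plateau removed: corrected tail below 5% of peak
  tail_idx <- (length(times) - 4):length(times)
  expect_gt(max(abs(leaky[tail_idx])), 0.05 * max(leaky))
  expect_lt(max(abs(r1$corrected[tail_idx])), 0.05 * max(r1$corrected))

  expect_error(correct_leakage(ref, rep(1, length(ref)), times), "degenerate")
})

test_that("perfusion indices follow the closed forms of the fitted curve", {
  f <- fit_gamma_variate(gamma_variate(seq(0, 15, 0.5), 1, 0, 2, 1),
                         seq(0, 15, 0.5))
  pin <- perfusion_indices(f)
  expect_equal(pin$cbv, 2, tolerance = 1e-6)
  expect_equal(pin$mtt, 3, tolerance = 1e-6)
  expect_equal(pin$ttp, 2, tolerance = 1e-6)
  expect_equal(pin$cbf, 2 / 3, tolerance = 1e-6)

  # doubling beta doubles MTT and TTP - t0
  f2 <- fit_gamma_variate(gamma_variate(seq(0, 30, 0.5), 1, 0, 2, 2),
                          seq(0, 30, 0.5))
  pin2 <- perfusion_indices(f2)
  expect_equal(pin2$mtt / pin$mtt, 2, tolerance = 1e-5)
  expect_equal((pin2$ttp - f2$t0) / (pin$ttp - f$t0), 2, tolerance = 1e-5)

  # area matches fine trapezoidal quadrature of the fitted curve
  f3 <- fit_gamma_variate(gamma_variate(seq(0, 40, 0.5), 7, 3, 2.5, 1.3),
                          seq(0, 40, 0.5))
  pin3 <- perfusion_indices(f3)
  tt <- seq(0, 10 * (f3$t0 + f3$alpha_g * f3$beta_g), by = 1e-3)
  yy <- gamma_variate(tt, f3$k_amp, f3$t0, f3$alpha_g, f3$beta_g)
  quad <- sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
  expect_equal(pin3$cbv, quad, tolerance = 1e-3)

  nc <- fit_gamma_variate(rep(0, 20))
  expect_true(all(is.na(unlist(perfusion_indices(nc)))))
})

test_that("simulated DSC round trip reproduces planted indices", {
  pars <- list(k_amp = 25, t0 = 10, alpha_g = 2, beta_g = 1.5)
  ser <- simulate_dsc_series(lapply(pars, function(v) array(v, c(2, 1, 1))),
                             dsc_pars(), recirculation = FALSE,
                             leakage_k2 = 0, noise_sd = 0)
  dr2 <- signal_to_relaxation(ser)
  ft <- fit_gamma_variate(dr2[, 1, 1, 1], ser$times)
  pin <- perfusion_indices(ft)
  expect_equal(pin$cbv, pars$k_amp * pars$beta_g^3 * gamma(3), tolerance = 1e-4)
  expect_equal(pin$mtt, pars$beta_g * 3, tolerance = 1e-4)
  expect_equal(pin$ttp, pars$t0 + 2 * pars$beta_g, tolerance = 1e-4)

  # scale equivariance through the whole chain
  ser2 <- ser
  ser2$data <- ser$data * 4.2
  ft2 <- fit_gamma_variate(signal_to_relaxation(ser2)[, 1, 1, 1], ser$times)
  expect_equal(unlist(perfusion_indices(ft2)), unlist(pin), tolerance = 1e-8)
})

test_that("relative normalization divides by the reference median", {
  m <- array(runif(64, 1, 9), c(4, 4, 4))
  ref <- array(FALSE, c(4, 4, 4)); ref[1:2, 1, 1] <- TRUE
  out <- normalize_relative(m, ref)
  expect_equal(out, m / median(m[ref]), tolerance = 1e-12)
  expect_equal(median(out[ref]), 1)

  cm <- m; cm[ref] <- 2.5
  expect_equal(normalize_relative(cm, ref), cm / 2.5)

  expect_error(normalize_relative(m, array(FALSE, c(4, 4, 4))), "empty")
  neg <- m; neg[ref] <- -1
  expect_error(normalize_relative(neg, ref), "median")
})

test_that("voxelwise perfusion maps agree with the single-curve path", {
  set.seed(3)
  K <- array(0, c(3, 3, 1)); K[] <- runif(9, 10, 40)
  truth <- list(k_amp = K, t0 = array(10, dim(K)), alpha_g = array(2, dim(K)),
                beta_g = array(1.5, dim(K)))
  ser <- simulate_dsc_series(truth, dsc_pars(), noise_sd = 0)
  mask <- array(TRUE, dim(K))
  ref <- array(FALSE, dim(K)); ref[1, 1, 1] <- TRUE
  pm <- compute_perfusion_maps(ser, mask, ref, leakage_correct = FALSE,
                               method = "nls")
  expect_true(all(pm$fit_quality))
  expect_equal(as.numeric(pm$rcbv), as.numeric(K * 1.5^3 * gamma(3)),
               tolerance = 1e-5)
  expect_equal(as.numeric(pm$mtt), rep(4.5, 9), tolerance = 1e-5)
})
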