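## Physiologic map computation: ADC from a two-b-value DWI pair, and
## DSC perfusion indices (rCBV, rCBF, MTT, TTP) from a dynamic series via
## gamma-variate first-pass fitting with recirculation windowing and
## model-based leakage correction.

#' Gamma-variate bolus curve
#'
#' The canonical first-pass shape for a contrast bolus:
#' \eqn{C(t) = K (t - t_0)^\alpha e^{-(t - t_0)/\beta}} for \eqn{t > t_0},
#' zero before bolus arrival.
#'
#' @param t times (s).
#' @param k_amp amplitude K (same units as the curve).
#' @param t0 bolus arrival time (s).
#' @param alpha_g shape exponent (dimensionless, > 0).
#' @param beta_g decay scale (s, > 0).
#' @return Curve values at `t`.
#' @export
gamma_variate <- function(t, k_amp, t0, alpha_g, beta_g) {
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- k_amp * dt[pos]^alpha_g * exp(-dt[pos] / beta_g)
  out
}

#' Apparent diffusion coefficient map from a two-b-value pair
#'
#' ADC = ln(S_b0 / S_b) / b per voxel, in mm^2/s for b in s/mm^2.
#' Negative estimates (noise pushing S_b above S_b0) are clamped to zero;
#' the number of clamped voxels is attached as attribute `"n_clamped"` and
#' a logical validity map (`TRUE` where no clamping occurred) as `"valid"`.
#'
#' @param s_b0 signal volume at b = 0 (array or vector).
#' @param s_b1000 signal volume at the high b-value, same shape.
#' @param b the high b-value (s/mm^2), default 1000.
#' @param mask optional logical array restricting evaluation; outside the
#'   mask the map is `NA`.
#' @return Numeric array of ADC values with attributes `n_clamped`, `valid`.
#' @export
compute_adc <- function(s_b0, s_b1000, b = 1000, mask = NULL) {
  check_scalar_num(b, "b", lower = 0, strict_lower = TRUE)
  if (!identical(dim(s_b0), dim(s_b1000)) || length(s_b0) != length(s_b1000))
    stop("b0 and b1000 volumes must share shape")
  if (is.null(mask)) mask <- rep(TRUE, length(s_b0))
  m <- as.logical(mask)
  bad <- m & (s_b0 <= 0 | s_b1000 <= 0)
  if (any(bad, na.rm = TRUE))
    stop(sprintf("non-positive signal inside mask at %d voxel(s)",
                 sum(bad, na.rm = TRUE)))
  adc <- rep(NA_real_, length(s_b0))
  adc[m] <- log(s_b0[m] / s_b1000[m]) / b
  clamped <- m & !is.na(adc) & adc < 0
  adc[clamped] <- 0
  dim(adc) <- dim(s_b0)
  valid <- !clamped & m
  dim(valid) <- dim(s_b0)
  structure(adc, n_clamped = sum(clamped), valid = valid)
}

#' Dynamic susceptibility contrast series
#'
#' Container for a DSC acquisition: a time-by-voxel signal array plus the
#' repetition/echo times and the pre-bolus baseline window.
#'
#' @param data numeric array with time as the first dimension (time x voxels,
#'   or a 4D time x X x Y x Z array).
#' @param tr repetition time (s).
#' @param te echo time (s).
#' @param baseline_window integer indices of pre-bolus timepoints.
#' @return An object of class `dsc_series`.
#' @export
dsc_series <- function(data, tr, te, baseline_window) {
  check_scalar_num(tr, "tr", lower = 0, strict_lower = TRUE)
  check_scalar_num(te, "te", lower = 0, strict_lower = TRUE)
  nt <- if (is.null(dim(data))) length(data) else dim(data)[1]
  if (nt < 10) stop_cfg("data", "needs at least 10 timepoints")
  bw <- as.integer(baseline_window)
  if (length(bw) == 0 || any(bw < 1) || any(bw > nt))
    stop_cfg("baseline_window", "must be a non-empty index range within the series")
  structure(list(data = data, tr = tr, te = te, baseline_window = bw,
                 times = (seq_len(nt) - 1) * tr),
            class = "dsc_series")
}

#' Convert DSC signal to relaxation-rate change
#'
#' \eqn{\Delta R_2^*(t) = -\ln(S(t)/S_{base}) / TE} with the baseline
#' signal taken as the mean over the pre-bolus window. The output baseline
#' is zero by construction; the curve is invariant to rescaling the signal.
#'
#' @param series a [dsc_series].
#' @return Array of the same shape as `series$data` holding
#'   \eqn{\Delta R_2^*} in 1/s.
#' @export
signal_to_relaxation <- function(series) {
  stopifnot(inherits(series, "dsc_series"))
  d <- series$data
  dm <- dim(d)
  nt <- if (is.null(dm)) length(d) else dm[1]
  x <- matrix(d, nrow = nt)
  sbase <- colMeans(x[series$baseline_window, , drop = FALSE])
  if (any(sbase <= 0, na.rm = TRUE))
    stop("non-positive baseline mean signal in series")
  out <- -log(sweep(x, 2, sbase, "/")) / series$te
  dim(out) <- dm
  out
}

## end of the recirculation-free fit window: first post-peak sample below
## `frac` of the peak (the whole curve if it never drops that far)
.gv_fit_window <- function(curve, frac) {
  p <- which.max(curve)
  if (p < length(curve)) {
    below <- which(curve[(p + 1):length(curve)] < frac * curve[p])
    if (length(below)) return(list(peak = p, end = p + below[1]))
  }
  list(peak = p, end = length(curve))
}

## bolus arrival init: last sample time before the curve exceeds 10% of peak
.gv_t0_init <- function(curve, times, peak_idx) {
  thr <- 0.1 * curve[peak_idx]
  rise <- which(curve[seq_len(peak_idx)] > thr)
  if (length(rise) == 0 || rise[1] <= 1) return(max(times[1], 0))
  times[rise[1] - 1]
}

## weighted log-linearised fit at fixed t0:
## log C = log K + alpha*log(t-t0) - (t-t0)/beta is linear in its coefficients
.gv_loglin <- function(curve, times, t0, iters = 3) {
  sel <- which(times > t0 & curve > max(curve) * 1e-3)
  if (length(sel) < 4) return(NULL)
  dt <- times[sel] - t0
  y <- log(curve[sel])
  X <- cbind(1, log(dt), -dt)
  w <- rep(1, length(sel))
  cf <- NULL
  for (i in seq_len(iters)) {
    Xw <- X * w
    cf <- tryCatch(drop(solve(crossprod(Xw, X), crossprod(Xw, y))),
                   error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf)) || cf[3] <= 0) return(NULL)
    # reweight by fitted concentration: equalises noise after the log
    w <- exp(2 * drop(X %*% cf))
  }
  list(k_amp = exp(cf[[1]]), t0 = t0, alpha_g = cf[[2]], beta_g = 1 / cf[[3]])
}

#' Fit a gamma-variate first-pass curve
#'
#' Least-squares fit of [gamma_variate] to a \eqn{\Delta R_2^*} curve.
#' To avoid the recirculation bump, only samples up to the first post-peak
#' return below `recirc_frac` of the peak enter the fit. Initial values come
#' from a log-linearised regression; `method = "nls"` refines them by
#' bounded Levenberg-Marquardt, `method = "loglin"` keeps the (iteratively
#' reweighted) log-linear solution — much faster, used for voxelwise maps.
#'
#' @param curve \eqn{\Delta R_2^*} samples (1/s).
#' @param times sample times (s), same length.
#' @param recirc_frac post-peak cutoff fraction of peak (default 0.2).
#' @param snr_min minimum peak-to-residual ratio for `converged` (default 5).
#' @param method `"nls"` (default) or `"loglin"`.
#' @return Object of class `gamma_variate_fit`: `k_amp`, `t0`, `alpha_g`,
#'   `beta_g`, `rss`, `converged`, and the fitted window indices.
#' @export
fit_gamma_variate <- function(curve, times = seq_along(curve) - 1,
                              recirc_frac = 0.2, snr_min = 5,
                              method = c("nls", "loglin")) {
  method <- match.arg(method)
  if (length(curve) < 8) stop("need at least 8 samples")
  if (length(curve) != length(times)) stop("curve and times differ in length")
  failed <- structure(list(k_amp = NA_real_, t0 = NA_real_, alpha_g = NA_real_,
                           beta_g = NA_real_, rss = sum(curve^2),
                           converged = FALSE, window = integer()),
                      class = "gamma_variate_fit")
  peak <- max(curve)
  if (!is.finite(peak) || peak <= 0 || stats::sd(curve) == 0) return(failed)
  win <- .gv_fit_window(curve, recirc_frac)
  idx <- seq_len(win$end)
  t0 <- .gv_t0_init(curve, times, win$peak)

  if (method == "loglin") {
    par <- .gv_loglin(curve[idx], times[idx], t0, iters = 3)
    if (is.null(par) || par$alpha_g <= 0) return(failed)
  } else {
    # profile the arrival time over nearby sample times with the
    # log-linearised fit, then refine all four parameters
    dt <- stats::median(diff(times))
    cand <- unique(pmax(0, c(t0, t0 - dt, t0 - 2 * dt, t0 + dt / 2)))
    cand <- cand[cand < times[win$peak]]
    inits <- lapply(cand, function(tc)
      .gv_loglin(curve[idx], times[idx], tc, iters = 2))
    rss_of <- function(p) {
      if (is.null(p) || p$alpha_g <= 0) return(Inf)
      sum((curve[idx] - gamma_variate(times[idx], p$k_amp, p$t0,
                                      p$alpha_g, p$beta_g))^2)
    }
    best <- inits[[which.min(vapply(inits, rss_of, 0))]]
    if (is.null(best) || best$alpha_g <= 0) return(failed)
    df <- data.frame(t = times[idx], y = curve[idx])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ gamma_variate(t, k, t0, a, b), data = df,
        start = list(k = best$k_amp, t0 = best$t0,
                     a = best$alpha_g, b = best$beta_g),
        lower = c(0, 0, 1e-6, 1e-6),
        upper = c(Inf, times[win$peak], Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))  # arrival-time kink can defeat the 4-parameter fit
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ gamma_variate(t, k, t0c, a, b),
          data = cbind(df, t0c = best$t0),
          start = list(k = best$k_amp, a = best$alpha_g, b = best$beta_g),
          lower = c(0, 1e-6, 1e-6),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) {
      par <- best
    } else {
      cf <- as.list(stats::coef(fit))
      par <- list(k_amp = cf$k, t0 = if (is.null(cf$t0)) best$t0 else cf$t0,
                  alpha_g = cf$a, beta_g = cf$b)
    }
  }
  resid <- curve[idx] - gamma_variate(times[idx], par$k_amp, par$t0,
                                      par$alpha_g, par$beta_g)
  rss <- sum(resid^2)
  snr <- peak / sqrt(rss / length(idx) + .Machine$double.eps)
  structure(list(k_amp = par$k_amp, t0 = par$t0, alpha_g = par$alpha_g,
                 beta_g = par$beta_g, rss = rss,
                 converged = is.finite(snr) && snr >= snr_min,
                 window = idx),
            class = "gamma_variate_fit")
}

#' @export
print.gamma_variate_fit <- function(x, ...) {
  if (!x$converged) {
    cat("gamma-variate fit: not converged\n")
  } else {
    cat(sprintf(
      "gamma-variate fit: K=%.4g, t0=%.3g s, alpha=%.4g, beta=%.4g s (rss %.3g)\n",
      x$k_amp, x$t0, x$alpha_g, x$beta_g, x$rss))
  }
  invisible(x)
}

## cumulative trapezoidal integral on an arbitrary time grid
.cumtrapz <- function(y, t) {
  n <- length(y)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

#' Model-based leakage correction of a DSC curve
#'
#' Two-parameter linear model in the Boxerman style: the voxel curve is
#' regressed on a non-leaky reference curve and its running integral,
#' `curve ~ k1 * reference - k2 * cumint(reference)`; adding back the `k2`
#' term removes the T1/T2* leakage ramp so the tail returns to baseline.
#'
#' @param curve voxel \eqn{\Delta R_2^*} samples.
#' @param reference whole-tissue mean \eqn{\Delta R_2^*} curve, same times.
#' @param times sample times (s).
#' @return List with `corrected` curve, `k1`, `k2`.
#' @export
correct_leakage <- function(curve, reference, times = seq_along(curve) - 1) {
  if (length(curve) != length(reference))
    stop("curve and reference must share the time axis")
  if (stats::sd(reference) == 0)
    stop("degenerate (constant) reference curve")
  ci <- .cumtrapz(reference, times)
  X <- cbind(reference, -ci)
  cf <- stats::lm.fit(X, curve)$coefficients
  k1 <- cf[[1]]; k2 <- cf[[2]]
  list(corrected = curve + k2 * ci, k1 = k1, k2 = k2)
}

#' Perfusion indices of a fitted first-pass curve
#'
#' Defined directly on the fitted gamma variate (no arterial input
#' deconvolution; the paper-style "relative" units):
#' CBV is the area under the curve, \eqn{K \beta^{\alpha+1} \Gamma(\alpha+1)};
#' MTT the first moment about \eqn{t_0} over the area, \eqn{\beta(\alpha+1)};
#' TTP the peak time \eqn{t_0 + \alpha\beta}; CBF = CBV / MTT by the central
#' volume principle.
#'
#' @param fit a `gamma_variate_fit`.
#' @return Named list `cbv`, `cbf`, `mtt`, `ttp` (all `NA` if not converged).
#' @export
perfusion_indices <- function(fit) {
  stopifnot(inherits(fit, "gamma_variate_fit"))
  if (!isTRUE(fit$converged))
    return(list(cbv = NA_real_, cbf = NA_real_, mtt = NA_real_, ttp = NA_real_))
  cbv <- fit$k_amp * fit$beta_g^(fit$alpha_g + 1) * gamma(fit$alpha_g + 1)
  mtt <- fit$beta_g * (fit$alpha_g + 1)
  list(cbv = cbv, cbf = cbv / mtt, mtt = mtt, ttp = fit$t0 + fit$alpha_g * fit$beta_g)
}

#' Voxelwise perfusion maps from a DSC series
#'
#' Runs signal-to-relaxation conversion, optional leakage correction against
#' the mean curve of `reference_mask`, gamma-variate fitting and index
#' computation for every voxel of `fit_mask`.
#'
#' @param series a [dsc_series] with 4D data (time x X x Y x Z).
#' @param fit_mask logical 3D array of voxels to fit.
#' @param reference_mask logical 3D array of normal tissue (leakage
#'   reference and normalization region).
#' @param leakage_correct apply [correct_leakage] per voxel (default TRUE).
#' @param method fit method passed to [fit_gamma_variate]; the fast
#'   `"loglin"` path is the default for maps.
#' @param recirc_frac,snr_min passed to [fit_gamma_variate].
#' @return Object of class `perfusion_map_set`: 3D arrays `rcbv`, `rcbf`,
#'   `mtt`, `ttp` (`NA` outside `fit_mask` / at failed fits), logical
#'   `fit_quality`, and `n_failed`.
#' @export
compute_perfusion_maps <- function(series, fit_mask, reference_mask,
                                   leakage_correct = TRUE,
                                   method = "loglin",
                                   recirc_frac = 0.2, snr_min = 5) {
  stopifnot(inherits(series, "dsc_series"))
  dm <- dim(series$data)
  if (length(dm) != 4) stop("series data must be 4D (time x X x Y x Z)")
  vol_dim <- dm[-1]
  if (!identical(dim(fit_mask), vol_dim) || !identical(dim(reference_mask), vol_dim))
    stop("masks must match the spatial grid of the series")
  dr2 <- signal_to_relaxation(series)
  dr2m <- matrix(dr2, nrow = dm[1])
  ref_curve <- rowMeans(dr2m[, which(reference_mask), drop = FALSE])
  times <- series$times
  vox <- which(fit_mask | reference_mask)
  if (leakage_correct) {
    # same two-parameter model as correct_leakage, solved for all voxels at
    # once: the design matrix depends only on the shared reference curve
    ci <- .cumtrapz(ref_curve, times)
    X <- cbind(ref_curve, -ci)
    k2 <- drop(solve(crossprod(X), crossprod(X, dr2m[, vox, drop = FALSE]))[2, ])
    dr2m[, vox] <- dr2m[, vox, drop = FALSE] + outer(ci, k2)
  }
  maps <- lapply(1:4, function(i) array(NA_real_, vol_dim))
  names(maps) <- c("rcbv", "rcbf", "mtt", "ttp")
  quality <- array(FALSE, vol_dim)
  for (v in vox) {
    curve <- dr2m[, v]
    fit <- fit_gamma_variate(curve, times, recirc_frac = recirc_frac,
                             snr_min = snr_min, method = method)
    if (fit$converged) {
      pin <- perfusion_indices(fit)
      maps$rcbv[v] <- pin$cbv; maps$rcbf[v] <- pin$cbf
      maps$mtt[v] <- pin$mtt;  maps$ttp[v] <- pin$ttp
      quality[v] <- TRUE
    }
  }
  structure(c(maps, list(fit_quality = quality,
                         n_failed = sum(!quality[vox]))),
            class = "perfusion_map_set")
}

#' Normalize a map to a reference region
#'
#' Divides every voxel by the median of the map over a reference (normal
#' tissue) mask, yielding the "r"-prefixed relative maps; the median is used
#' rather than the mean for robustness. The output has median exactly 1
#' over the reference.
#'
#' @param map numeric array.
#' @param reference_mask logical array, same grid, non-empty.
#' @return Array of relative values.
#' @export
normalize_relative <- function(map, reference_mask) {
  if (!any(reference_mask)) stop("empty reference mask")
  ref <- map[reference_mask]
  med <- stats::median(ref, na.rm = TRUE)
  if (!is.finite(med) || med <= 0)
    stop("reference median is non-positive or undefined")
  map / med
}
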