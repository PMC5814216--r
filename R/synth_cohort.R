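## Fully synthetic radiogenomic cohort with known ground truth.
## Three latent subtypes are expressed jointly in imaging (perfusion,
## diffusion, volume), expression (disjoint marker-gene blocks), sparse
## mutations/CNV, and exponential survival, so every downstream stage of
## the pipeline can be tested without any patient data.

#' Subtype generative profile
#'
#' Ground-truth parameters of one latent tumor subtype: tissue-level
#' gamma-variate perfusion parameters, diffusivity, geometry, expression
#' marker block, mutation/CNV spectrum and survival hazard.
#'
#' @param name label for the subtype.
#' @param prevalence mixture fraction in `[0, 1]`.
#' @param perfusion_params named list with numeric `k_amp`, `t0` (s),
#'   `alpha_g`, `beta_g` (s) for tumor tissue.
#' @param adc_mean tumor diffusivity (mm^2/s).
#' @param tumor_radius_mm radius of the contrast-enhancing sphere (mm).
#' @param marker_block character vector of marker gene ids.
#' @param expression_delta log2-scale mean shift of the marker block.
#' @param mutation_rates named per-gene Bernoulli probabilities.
#' @param cnv_segments named per-gene log2 copy-number means.
#' @param hazard exponential event rate (1/month).
#' @param param_cv named lognormal coefficients of patient-level variation
#'   around the profile means for `k_amp`, `beta_g` and `adc`. A single
#'   latent per-patient severity drives all three jointly (more aggressive
#'   tumors are more perfused, more cellular and faster-transit), so
#'   within-subtype heterogeneity lies along the biological axis linking
#'   the low- and high-perfusion subtypes.
#' @return Object of class `subtype_profile`.
#' @export
subtype_profile <- function(name, prevalence, perfusion_params, adc_mean,
                            tumor_radius_mm, marker_block, expression_delta,
                            mutation_rates, cnv_segments, hazard,
                            param_cv = c(k_amp = 0.25, beta_g = 0.06,
                                         adc = 0.10)) {
  check_scalar_num(prevalence, "prevalence", 0, 1)
  for (f in c("k_amp", "t0", "alpha_g", "beta_g"))
    if (is.null(perfusion_params[[f]]))
      stop_cfg("perfusion_params", sprintf("is missing '%s'", f))
  check_scalar_num(perfusion_params$k_amp, "perfusion_params$k_amp", 0, strict_lower = TRUE)
  check_scalar_num(perfusion_params$alpha_g, "perfusion_params$alpha_g", 0, strict_lower = TRUE)
  check_scalar_num(perfusion_params$beta_g, "perfusion_params$beta_g", 0, strict_lower = TRUE)
  check_scalar_num(adc_mean, "adc_mean", 0, strict_lower = TRUE)
  check_scalar_num(tumor_radius_mm, "tumor_radius_mm", 0, strict_lower = TRUE)
  check_scalar_num(hazard, "hazard", 0, strict_lower = TRUE)
  structure(list(name = name, prevalence = prevalence,
                 perfusion_params = perfusion_params, adc_mean = adc_mean,
                 tumor_radius_mm = tumor_radius_mm,
                 marker_block = as.character(marker_block),
                 expression_delta = expression_delta,
                 mutation_rates = mutation_rates,
                 cnv_segments = cnv_segments, hazard = hazard,
                 param_cv = param_cv),
            class = "subtype_profile")
}

#' Default three-subtype generative profiles
#'
#' Qualitative mimics of the three radiomic clusters reported for
#' glioblastoma: a "mesenchymal-like" profile with high CBV/CBF, low ADC and
#' the worst prognosis; a "proneural/neural-like" profile with low perfusion
#' and high ADC; and a "classical-like" intermediate profile with the
#' largest tumor volume. Per-subtype median survivals (14, 20, 9 months)
#' put the cohort median near 13.2 months.
#'
#' @param n_marker number of marker genes per subtype (default 50).
#' @return List of three [subtype_profile] objects.
#' @export
default_profiles <- function(n_marker = 50) {
  gid <- function(i) sprintf("gene_%04d", i)
  blocks <- list(classical = gid(1:n_marker),
                 proneural_neural = gid(n_marker + 1:n_marker),
                 mesenchymal = gid(2 * n_marker + 1:n_marker))
  base_mut <- c(EGFR = 0.05, TP53 = 0.05, PTEN = 0.05, NF1 = 0.05,
                PDGFRA = 0.05, IDH1 = 0.02, RB1 = 0.05, PIK3CA = 0.05,
                ATRX = 0.05, CDKN2A = 0.05)
  base_cnv <- c(EGFR = 0, PDGFRA = 0, CDKN2A = -0.3, NF1 = 0, MDM2 = 0,
                CDK4 = 0, MET = 0, RB1 = 0)
  list(
    subtype_profile(
      name = "classical", prevalence = 0.32,
      perfusion_params = list(k_amp = 32.5, t0 = 10, alpha_g = 2, beta_g = 1.51),
      adc_mean = 0.95e-3, tumor_radius_mm = 10,
      marker_block = blocks$classical, expression_delta = 2,
      mutation_rates = replace(base_mut, "EGFR", 0.5),
      cnv_segments = replace(base_cnv, "EGFR", 1.5),
      hazard = log(2) / 14,
      # the intermediate subtype is physiologically the most heterogeneous:
      # its patients scatter between the two extreme profiles
      param_cv = c(k_amp = 0.35, beta_g = 0.08, adc = 0.14)),
    subtype_profile(
      name = "proneural_neural", prevalence = 0.31,
      perfusion_params = list(k_amp = 8.6, t0 = 10, alpha_g = 2, beta_g = 1.9),
      adc_mean = 1.3e-3, tumor_radius_mm = 6.5,
      marker_block = blocks$proneural_neural, expression_delta = 2,
      mutation_rates = replace(base_mut, c("PDGFRA", "TP53", "IDH1"),
                               c(0.35, 0.5, 0.1)),
      cnv_segments = replace(base_cnv, "PDGFRA", 1.0),
      hazard = log(2) / 20),
    subtype_profile(
      name = "mesenchymal", prevalence = 0.37,
      perfusion_params = list(k_amp = 85, t0 = 10, alpha_g = 2, beta_g = 1.2),
      adc_mean = 0.7e-3, tumor_radius_mm = 6.5,
      marker_block = blocks$mesenchymal, expression_delta = 2,
      mutation_rates = replace(base_mut, c("NF1", "PTEN"), c(0.45, 0.4)),
      cnv_segments = replace(base_cnv, "NF1", -0.8),
      hazard = log(2) / 9))
}

#' Cohort simulation configuration
#'
#' @param n_patients cohort size (default 65).
#' @param profiles list of [subtype_profile]; prevalences must sum to 1 and
#'   marker blocks must be pairwise disjoint.
#' @param grid_shape voxel grid dimensions (default 32 x 32 x 32).
#' @param voxel_spacing (dx, dy, dz) in mm (default 1 x 1 x 5: 5 mm slices).
#' @param dsc_params list `tr` (s), `te` (s), `n_timepoints`,
#'   `baseline_window` (default TR/TE 1.72/0.035 s, 50 volumes).
#' @param b_values the DWI b-value pair, s/mm^2 (default c(0, 1000)).
#' @param noise_sd named per-modality noise scales: `dwi`, `dsc` (signal
#'   units), `expression` (log2 units), `cnv` (log2 units).
#' @param n_genes size of the gene universe for expression.
#' @param baseline_mean baseline log2 expression level.
#' @param leakage_k2 leakage rate applied to tumor voxels in the DSC
#'   forward model (1/s).
#' @param censoring_rate expected fraction of censored patients in `[0, 1)`.
#' @param seed RNG seed for the whole cohort.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 65,
                          profiles = default_profiles(),
                          grid_shape = c(32, 32, 32),
                          voxel_spacing = c(1, 1, 5),
                          dsc_params = list(tr = 1.72, te = 0.035,
                                            n_timepoints = 50,
                                            baseline_window = 1:5),
                          b_values = c(0, 1000),
                          noise_sd = c(dwi = 5, dsc = 1,
                                       expression = 1, cnv = 0.3),
                          n_genes = 1000,
                          baseline_mean = 3,
                          leakage_k2 = 0.02,
                          censoring_rate = 0.29,
                          seed = 1L) {
  if (length(profiles) < 1) stop_cfg("profiles", "must be non-empty")
  if (!all(vapply(profiles, inherits, TRUE, "subtype_profile")))
    stop_cfg("profiles", "must all be subtype_profile objects")
  prev <- vapply(profiles, `[[`, 0, "prevalence")
  if (abs(sum(prev) - 1) > 1e-8)
    stop_cfg("profiles", "prevalences must sum to 1")
  blocks <- lapply(profiles, `[[`, "marker_block")
  if (length(unlist(blocks)) != length(unique(unlist(blocks))))
    stop_cfg("profiles", "marker blocks must be pairwise disjoint")
  if (n_patients < length(profiles))
    stop_cfg("n_patients", "must be at least the number of profiles")
  if (any(voxel_spacing <= 0)) stop_cfg("voxel_spacing", "must be positive")
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop_cfg("grid_shape", "must be three dimensions of at least 4 voxels")
  if (dsc_params$n_timepoints < 10)
    stop_cfg("dsc_params$n_timepoints", "must be at least 10")
  if (n_genes < length(unique(unlist(blocks))))
    stop_cfg("n_genes", "must cover the union of marker blocks")
  check_scalar_num(censoring_rate, "censoring_rate", 0, 1, strict_upper = TRUE)
  structure(list(n_patients = as.integer(n_patients), profiles = profiles,
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = voxel_spacing, dsc_params = dsc_params,
                 b_values = b_values, noise_sd = noise_sd,
                 n_genes = as.integer(n_genes), baseline_mean = baseline_mean,
                 leakage_k2 = leakage_k2, censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## ellipsoid mask on the voxel grid; centre and semi-axes in mm
.ellipsoid_mask <- function(grid_shape, spacing, center_mm, semiaxes_mm) {
  ax <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  ay <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  az <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  dx2 <- ((ax - center_mm[1]) / semiaxes_mm[1])^2
  dy2 <- ((ay - center_mm[2]) / semiaxes_mm[2])^2
  dz2 <- ((az - center_mm[3]) / semiaxes_mm[3])^2
  array(outer(outer(dx2, dy2, "+"), dz2, "+") <= 1, grid_shape)
}

#' Simulate a two-b-value DWI pair from an ADC truth map
#'
#' Mono-exponential diffusion decay \eqn{S_b = S_0 e^{-b \cdot ADC}} with
#' additive Gaussian noise.
#'
#' @param adc_truth non-negative voxel map of true diffusivity (mm^2/s).
#' @param s0 baseline signal intensity (> 0).
#' @param b_values length-2 vector of b-values (s/mm^2).
#' @param noise_sd Gaussian noise SD in signal units (0 = noiseless).
#' @return List with volumes `b0` and `b1000` (named after the b-values).
#' @export
simulate_dwi_pair <- function(adc_truth, s0 = 1000, b_values = c(0, 1000),
                              noise_sd = 0) {
  if (any(adc_truth < 0)) stop("adc_truth must be non-negative everywhere")
  check_scalar_num(s0, "s0", 0, strict_lower = TRUE)
  mk <- function(b) {
    v <- s0 * exp(-b * adc_truth)
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    dim(v) <- dim(adc_truth)
    v
  }
  list(b0 = mk(b_values[1]), b1000 = mk(b_values[2]))
}

#' Simulate a DSC signal series from voxelwise gamma-variate truth
#'
#' Forward model \eqn{S(t) = S_0 e^{-TE \cdot \Delta R_2^*(t)}} where
#' \eqn{\Delta R_2^*} is the first-pass gamma variate, plus an optional
#' delayed recirculation bump and an optional leakage ramp
#' \eqn{-k_2 \int_0^t C}. With zero noise, no recirculation and no leak
#' the series is exactly inverted by [signal_to_relaxation].
#'
#' @param true_params list of equal-shape numeric arrays `k_amp`, `t0`,
#'   `alpha_g`, `beta_g` (voxel maps or vectors).
#' @param dsc_params list `tr`, `te`, `n_timepoints`, `baseline_window`.
#' @param recirculation add a delayed second pass at 15% amplitude.
#' @param leakage_k2 leakage rate (1/s), scalar or per-voxel.
#' @param noise_sd Gaussian signal noise SD.
#' @param s0 pre-bolus signal level.
#' @return A [dsc_series]; data shaped time x voxel dims of the inputs.
#' @export
simulate_dsc_series <- function(true_params, dsc_params,
                                recirculation = FALSE, leakage_k2 = 0,
                                noise_sd = 0, s0 = 100) {
  K <- true_params$k_amp
  shp <- dim(K)
  nv <- length(K)
  t0 <- rep_len(as.numeric(true_params$t0), nv)
  a <- rep_len(as.numeric(true_params$alpha_g), nv)
  b <- rep_len(as.numeric(true_params$beta_g), nv)
  k2 <- rep_len(as.numeric(leakage_k2), nv)
  nt <- dsc_params$n_timepoints
  times <- (seq_len(nt) - 1) * dsc_params$tr
  need <- max(t0 + 5 * a * b)
  if (max(times) < need)
    stop(sprintf("time window too short: covers %.1f s, need %.1f s",
                 max(times), need))
  C <- matrix(0, nt, nv)
  active <- which(K > 0)
  # the curve is linear in K, so voxels sharing (t0, alpha, beta, k2) share
  # a unit shape; group them to vectorize over whole tissue compartments
  key <- paste(t0[active], a[active], b[active], k2[active])
  for (grp in split(active, key)) {
    v1 <- grp[1]
    shape <- gamma_variate(times, 1, t0[v1], a[v1], b[v1])
    if (recirculation)
      shape <- shape + gamma_variate(times, 0.15, t0[v1] + a[v1] * b[v1] + 8,
                                     a[v1], 2 * b[v1])
    if (k2[v1] != 0) shape <- shape - k2[v1] * .cumtrapz(shape, times)
    C[, grp] <- outer(shape, K[grp])
  }
  S <- s0 * exp(-dsc_params$te * C)
  if (noise_sd > 0) {
    S <- S + stats::rnorm(length(S), 0, noise_sd)
    # magnitude images are non-negative; floor emulates the Rician bound
    S <- pmax(S, 1e-3 * s0)
  }
  dim(S) <- c(nt, if (is.null(shp)) nv else shp)
  dsc_series(S, tr = dsc_params$tr, te = dsc_params$te,
             baseline_window = dsc_params$baseline_window)
}

#' Simulate a log-scale expression matrix with planted marker blocks
#'
#' Genes x patients matrix of Gaussian log2 expression around
#' `baseline_mean`; genes in a subtype's marker block are shifted by that
#' subtype's `expression_delta` in its patients only.
#'
#' @param labels per-patient subtype names.
#' @param profiles list of [subtype_profile].
#' @param n_genes gene universe size (ids `gene_0001` ...).
#' @param baseline_mean baseline log2 level.
#' @param noise_sd Gaussian noise SD (log2 units).
#' @param seed RNG seed.
#' @return Genes x patients matrix with dimnames, attribute
#'   `transform_tag = "log"`.
#' @export
simulate_expression <- function(labels, profiles, n_genes = 1000,
                                baseline_mean = 3, noise_sd = 1, seed = 1L) {
  blocks <- lapply(profiles, `[[`, "marker_block")
  names(blocks) <- vapply(profiles, `[[`, "", "name")
  all_markers <- unlist(blocks)
  if (length(all_markers) != length(unique(all_markers)))
    stop("overlapping marker blocks")
  if (n_genes < length(all_markers))
    stop("n_genes smaller than the union of marker blocks")
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  if (!all(all_markers %in% genes))
    stop("marker blocks outside the gene universe")
  set.seed(seed)
  n <- length(labels)
  x <- matrix(stats::rnorm(n_genes * n, baseline_mean, noise_sd),
              n_genes, n, dimnames = list(genes, sprintf("P%03d", seq_len(n))))
  for (p in profiles) {
    cols <- which(labels == p$name)
    if (length(cols) && length(p$marker_block))
      x[p$marker_block, cols] <- x[p$marker_block, cols] + p$expression_delta
  }
  structure(x, transform_tag = "log")
}

#' Simulate a binary somatic-mutation matrix
#'
#' Independent per-gene Bernoulli calls with subtype-specific rates.
#'
#' @inheritParams simulate_expression
#' @return Genes x patients 0/1 matrix.
#' @export
simulate_mutations <- function(labels, profiles, seed = 1L) {
  set.seed(seed)
  genes <- names(profiles[[1]]$mutation_rates)
  n <- length(labels)
  x <- matrix(0L, length(genes), n,
              dimnames = list(genes, sprintf("P%03d", seq_len(n))))
  for (p in profiles) {
    cols <- which(labels == p$name)
    for (j in cols)
      x[, j] <- stats::rbinom(length(genes), 1, p$mutation_rates[genes])
  }
  x
}

#' Simulate a gene-level log2 copy-number matrix
#'
#' Gaussian log2 copy-number values around subtype-specific segment means.
#'
#' @inheritParams simulate_expression
#' @param noise_sd Gaussian noise SD (log2 units).
#' @return Genes x patients numeric matrix.
#' @export
simulate_cnv <- function(labels, profiles, noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  genes <- names(profiles[[1]]$cnv_segments)
  n <- length(labels)
  x <- matrix(0, length(genes), n,
              dimnames = list(genes, sprintf("P%03d", seq_len(n))))
  for (p in profiles) {
    cols <- which(labels == p$name)
    for (j in cols)
      x[, j] <- stats::rnorm(length(genes), p$cnv_segments[genes], noise_sd)
  }
  x
}

#' Simulate exponential survival with independent censoring
#'
#' Event times are exponential with each subtype's hazard; censoring is an
#' independent exponential race calibrated so the expected censored
#' fraction equals `censoring_rate`.
#'
#' @param labels per-patient subtype names.
#' @param profiles list of [subtype_profile] (supplies hazards, 1/month).
#' @param censoring_rate expected censored fraction in `[0, 1)`.
#' @param seed RNG seed.
#' @return `data.frame` with `patient_id`, `time` (months), `event`
#'   (logical), `group` (the true subtype; downstream code may overwrite
#'   with discovered clusters).
#' @export
simulate_survival <- function(labels, profiles, censoring_rate = 0, seed = 1L) {
  check_scalar_num(censoring_rate, "censoring_rate", 0, 1, strict_upper = TRUE)
  hz <- vapply(profiles, `[[`, 0, "hazard")
  names(hz) <- vapply(profiles, `[[`, "", "name")
  if (any(hz <= 0)) stop("hazards must be positive")
  set.seed(seed)
  n <- length(labels)
  lambda <- hz[labels]
  t_event <- stats::rexp(n, lambda)
  if (censoring_rate > 0) {
    lam_c <- lambda * censoring_rate / (1 - censoring_rate)
    t_cens <- stats::rexp(n, lam_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             time = pmin(t_event, t_cens),
             event = t_event <= t_cens,
             group = labels,
             stringsAsFactors = FALSE)
}

## per-patient imaging record: masks, truth maps, DWI pair, DSC series;
## `severity` is the patient's latent aggressiveness z-score (drawn at
## cohort level as stratified quantiles for Monte-Carlo variance reduction)
.simulate_patient_imaging <- function(config, profile, patient_seed,
                                      severity = NULL) {
  set.seed(patient_seed)
  if (is.null(severity)) severity <- stats::rnorm(1)
  gs <- config$grid_shape; sp <- config$voxel_spacing
  extent <- gs * sp
  center <- extent / 2 + stats::runif(3, -1, 1) * c(0.5, 0.5, sp[3] / 2)
  r1 <- profile$tumor_radius_mm * stats::runif(1, 0.95, 1.05)
  t1ce_mask <- .ellipsoid_mask(gs, sp, center, rep(r1, 3))
  flair_ax <- r1 * c(1.35, 1.35, 1.2) * stats::runif(3, 0.97, 1.03)
  t2flair_mask <- .ellipsoid_mask(gs, sp, center, flair_ax) | t1ce_mask
  necrosis_mask <- .ellipsoid_mask(gs, sp, center, rep(0.45 * r1, 3))
  vess_center <- center + c(r1 * 0.9, 0, 0)
  vessel_mask <- .ellipsoid_mask(gs, sp, vess_center, rep(2.5, 3))
  # normal-tissue reference box in a corner, clear of the tumor
  ref_mask <- array(FALSE, gs)
  ref_mask[3:8, 3:8, 2:4] <- TRUE
  ref_mask <- ref_mask & !t2flair_mask

  # patient-level biological variability: one latent severity scales
  # perfusion up and diffusivity/transit down together
  cv <- profile$param_cv
  adc_pat <- profile$adc_mean * exp(-cv[["adc"]] * severity)
  k_pat <- profile$perfusion_params$k_amp * exp(cv[["k_amp"]] * severity)
  beta_pat <- profile$perfusion_params$beta_g * exp(-cv[["beta_g"]] * severity)

  # diffusion truth: normal 0.8e-3, edema elevated, tumor per profile,
  # necrotic core free-water-like
  adc <- array(0.8e-3, gs)
  edema <- t2flair_mask & !t1ce_mask
  adc[edema] <- (adc_pat + 1.4e-3) / 2
  adc[t1ce_mask] <- adc_pat
  adc[necrosis_mask] <- 2.2e-3
  adc <- adc * array(exp(stats::rnorm(length(adc), 0, 0.03)), gs)

  dwi <- simulate_dwi_pair(adc, s0 = 1000, b_values = config$b_values,
                           noise_sd = config$noise_sd[["dwi"]])

  # perfusion truth: normal-tissue amplitude 12 at beta 1.6; edema blood
  # volume halfway between normal tissue and tumor at the tumor's beta
  pp <- profile$perfusion_params
  t0 <- pp$t0 + stats::runif(1, -0.8, 0.8)
  K <- array(12, gs)
  k_normal_eq <- 12 * (1.6 / beta_pat)^3
  K[edema] <- (k_normal_eq + k_pat) / 2
  K[t1ce_mask] <- k_pat
  K[necrosis_mask] <- 3
  K[vessel_mask] <- 30
  K <- K * array(exp(stats::rnorm(length(K), 0, 0.05)), gs)
  beta <- array(1.6, gs)
  beta[t2flair_mask] <- beta_pat
  k2 <- array(0, gs)
  k2[t2flair_mask] <- config$leakage_k2
  truth <- list(k_amp = K, t0 = array(t0, gs), alpha_g = array(pp$alpha_g, gs),
                beta_g = beta)
  dsc <- simulate_dsc_series(truth, config$dsc_params, recirculation = TRUE,
                             leakage_k2 = k2,
                             noise_sd = config$noise_sd[["dsc"]], s0 = 100)

  t1ce <- array(100, gs) + 80 * t1ce_mask - 60 * necrosis_mask +
    array(stats::rnorm(prod(gs), 0, 2), gs)
  t2flair <- array(100, gs) + 70 * t2flair_mask +
    array(stats::rnorm(prod(gs), 0, 2), gs)

  structure(list(t1ce = t1ce, t2flair = t2flair,
                 t1ce_mask = t1ce_mask, t2flair_mask = t2flair_mask,
                 necrosis_mask = necrosis_mask, vessel_mask = vessel_mask,
                 reference_mask = ref_mask,
                 dwi_b0 = dwi$b0, dwi_b1000 = dwi$b1000, dsc = dsc,
                 adc_truth = adc, perfusion_truth = truth,
                 spacing = sp, b_values = config$b_values),
            class = "patient_imaging")
}

#' Simulate a complete radiogenomic cohort
#'
#' Draws subtype labels from the configured prevalences, then generates for
#' every patient: structural volumes and ROI masks (contrast-enhancing
#' sphere nested in a FLAIR ellipsoid, with necrotic core and vessel to
#' exercise mask subtraction), a two-b-value DWI pair, a DSC time series,
#' plus cohort-level expression, mutation, copy-number and survival tables.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [cohort_config].
#' @return Object of class `synthetic_cohort`: `imaging` (list of
#'   per-patient records), `expression`, `mutations`, `cnv`, `survival`,
#'   `truth` (labels, marker genes, hazards, per-patient map parameters),
#'   and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- config$profiles
  prev <- vapply(profiles, `[[`, 0, "prevalence")
  pnames <- vapply(profiles, `[[`, "", "name")
  set.seed(config$seed)
  # deterministic largest-remainder allocation of the prevalences, so the
  # cohort composition is exactly the configured mixture; order randomized
  n <- config$n_patients
  counts <- floor(prev * n)
  rem <- prev * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  labels <- sample(rep(pnames, counts))
  # latent severities: stratified normal quantiles within each subtype
  # (every cohort realizes the same within-subtype spread), shuffled
  severity <- numeric(config$n_patients)
  for (p in pnames) {
    idx <- which(labels == p)
    # lightly truncated quantile grid: heterogeneity without lone outliers
    q <- stats::qnorm(0.06 + 0.88 * (seq_along(idx) - 0.5) / length(idx))
    severity[idx] <- sample(q)
  }
  imaging <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    prof <- profiles[[match(labels[i], pnames)]]
    imaging[[i]] <- .simulate_patient_imaging(config, prof,
                                              child_seed(config$seed, i),
                                              severity = severity[i])
  }
  names(imaging) <- sprintf("P%03d", seq_len(config$n_patients))
  expr <- simulate_expression(labels, profiles, n_genes = config$n_genes,
                              baseline_mean = config$baseline_mean,
                              noise_sd = config$noise_sd[["expression"]],
                              seed = child_seed(config$seed, 100001L))
  mut <- simulate_mutations(labels, profiles,
                            seed = child_seed(config$seed, 100002L))
  cnv <- simulate_cnv(labels, profiles, noise_sd = config$noise_sd[["cnv"]],
                      seed = child_seed(config$seed, 100003L))
  surv <- simulate_survival(labels, profiles,
                            censoring_rate = config$censoring_rate,
                            seed = child_seed(config$seed, 100004L))
  truth <- list(subtype_labels = stats::setNames(labels, names(imaging)),
                marker_genes = stats::setNames(
                  lapply(profiles, `[[`, "marker_block"), pnames),
                true_hazards = stats::setNames(
                  vapply(profiles, `[[`, 0, "hazard"), pnames))
  structure(list(imaging = imaging, expression = expr, mutations = mut,
                 cnv = cnv, survival = surv, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic radiogenomic cohort: %d patients, %d subtypes, %d genes\n",
              length(x$imaging), length(x$config$profiles),
              nrow(x$expression)))
  print(table(x$truth$subtype_labels))
  invisible(x)
}
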