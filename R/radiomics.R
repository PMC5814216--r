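## The 82-feature first-order/volumetric radiomic profile: a fixed registry
## (12 volume/size features + 7 histogram statistics x 5 maps x 2 ROI bases)
## and its extraction from physiologic maps within tumor masks.

.HIST_STATS <- c(MEAN = "mean", MEDIAN = "median", SD = "sd",
                 X5P = "p5", X95P = "p95", Q1 = "q1", Q3 = "q3")
.HIST_MAPS <- c("rCBF", "rCBV", "MTT", "TTP", "rADC")

#' Region-of-interest mask
#'
#' @param voxels logical 3D array.
#' @param basis which structural image defined the ROI: `"T1CE"` or
#'   `"T2FLAIR"`.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, basis = c("T1CE", "T2FLAIR"),
                     spacing = c(1, 1, 5)) {
  basis <- match.arg(basis)
  if (!is.logical(voxels)) storage.mode(voxels) <- "logical"
  if (any(spacing <= 0)) stop_cfg("spacing", "must be positive")
  structure(list(voxels = voxels, basis = basis, spacing = spacing),
            class = "roi_mask")
}

#' The 82-entry radiomic feature registry
#'
#' Returns the full feature table in its canonical order: 12 volume/size
#' entries (pixel count, in-plane area in cm^2 and volume in mL for the
#' contrast-enhancing and FLAIR ROIs, and their ADC-valid counterparts),
#' then 7 histogram statistics (mean, median, SD, 5th/95th percentile,
#' quartiles) for each of the five physiologic maps (rCBF, rCBV, MTT, TTP,
#' rADC) on each of the two ROI bases. Names match the published parameter
#' table verbatim (including its `T2FALIR_VOL` spelling).
#'
#' @return `data.frame` with columns `name`, `source_map`, `roi_basis`,
#'   `statistic`; exactly 82 uniquely named rows.
#' @export
feature_registry <- function() {
  vol <- data.frame(
    name = c("T1CE_PIXEL", "T1CE_AREA", "T1CE_VOL",
             "T2FLAIR_PIXEL", "T2FLAIR_AREA", "T2FALIR_VOL",
             "rADCnT1_PIXEL", "rADCnT1_AREA", "rADCnT1_VOL",
             "rADCnT2_PIXEL", "rADCnT2_AREA", "rADCnT2_VOL"),
    source_map = rep(c("T1CE-mask", "T2FLAIR-mask", "rADC", "rADC"),
                     each = 3),
    roi_basis = rep(c("T1CE", "T2FLAIR", "T1CE", "T2FLAIR"), each = 3),
    statistic = rep(c("pixel_count", "area_cm2", "volume_ml"), 4),
    stringsAsFactors = FALSE)
  hist <- do.call(rbind, lapply(.HIST_MAPS, function(m) {
    do.call(rbind, lapply(c("T1", "T2"), function(r) {
      data.frame(name = sprintf("%sn%s_%s", m, r, names(.HIST_STATS)),
                 source_map = m,
                 roi_basis = if (r == "T1") "T1CE" else "T2FLAIR",
                 statistic = unname(.HIST_STATS),
                 stringsAsFactors = FALSE)
    }))
  }))
  rbind(vol, hist)
}

#' Subtract necrosis and vessel voxels from an ROI
#'
#' Set difference `roi \ (necrosis U vessels)`; the ROI basis is preserved.
#' An ROI left empty by the subtraction is unusable and raises an error.
#'
#' @param roi a [roi_mask].
#' @param necrosis,vessels logical arrays (or `roi_mask`s) on the same grid.
#' @return A [roi_mask].
#' @export
subtract_exclusions <- function(roi, necrosis = NULL, vessels = NULL) {
  stopifnot(inherits(roi, "roi_mask"))
  vox <- roi$voxels
  as_arr <- function(m) if (inherits(m, "roi_mask")) m$voxels else m
  for (m in list(necrosis, vessels)) {
    if (is.null(m)) next
    m <- as_arr(m)
    if (!identical(dim(m), dim(vox))) stop("exclusion mask grid mismatch")
    vox <- vox & !m
  }
  if (!any(vox)) stop("ROI empty after exclusion subtraction")
  roi_mask(vox, roi$basis, roi$spacing)
}

#' Volume and size features of an ROI
#'
#' @param roi a [roi_mask] (non-empty).
#' @return List `pixel_count` (voxels), `area_cm2` (total in-plane area
#'   over all slices, count * dx * dy / 100), `volume_ml`
#'   (count * dx * dy * dz / 1000).
#' @export
volume_features <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  n <- sum(roi$voxels)
  if (n == 0) stop("empty ROI mask")
  sp <- roi$spacing
  list(pixel_count = n,
       area_cm2 = n * sp[1] * sp[2] / 100,
       volume_ml = n * sp[1] * sp[2] * sp[3] / 1000)
}

#' First-order histogram statistics of a map inside an ROI
#'
#' Statistics over the valid (non-missing) ROI voxels only. Percentiles use
#' linear interpolation between order statistics with inclusive endpoints;
#' the SD uses the n-1 denominator. More than half the ROI missing (e.g.
#' failed perfusion fits) triggers a warning.
#'
#' @param map numeric array (may contain `NA` at invalid voxels).
#' @param roi a [roi_mask] or logical array on the same grid.
#' @return List `mean`, `median`, `sd`, `p5`, `p95`, `q1`, `q3`.
#' @export
histogram_features <- function(map, roi) {
  vox <- if (inherits(roi, "roi_mask")) roi$voxels else roi
  if (!identical(dim(map), dim(vox))) stop("map and ROI grid mismatch")
  vals <- map[vox]
  ok <- is.finite(vals)
  if (sum(!ok) / max(length(vals), 1) > 0.5)
    warning(sprintf("%d of %d ROI voxels missing", sum(!ok), length(vals)))
  vals <- vals[ok]
  if (length(vals) < 2)
    stop("fewer than 2 valid voxels in ROI")
  q <- stats::quantile(vals, c(0.05, 0.25, 0.75, 0.95), names = FALSE, type = 7)
  list(mean = mean(vals), median = stats::median(vals), sd = stats::sd(vals),
       p5 = q[1], p95 = q[4], q1 = q[2], q3 = q[3])
}

#' Extract the full 82-feature vector for one patient
#'
#' Applies the registry to the patient's maps and ROIs: volume features from
#' the mask geometry, ADC-valid volume features from the ADC validity map,
#' and histogram features of each physiologic map on each ROI basis.
#'
#' @param maps named list with numeric arrays `rADC`, `rCBF`, `rCBV`,
#'   `MTT`, `TTP` (NA marks invalid voxels). The `rADC` entry may carry a
#'   logical `"valid"` attribute (from [compute_adc]); otherwise
#'   non-missingness is used.
#' @param rois named list with [roi_mask]s `T1CE` and `T2FLAIR` (already
#'   exclusion-subtracted).
#' @return Named numeric vector of length 82 in registry order.
#' @export
extract_patient_features <- function(maps, rois) {
  reg <- feature_registry()
  need <- setdiff(unique(reg$source_map), c("T1CE-mask", "T2FLAIR-mask"))
  missing_maps <- setdiff(need, names(maps))
  if (length(missing_maps))
    stop(sprintf("missing map(s) %s; affected features: %s",
                 paste(missing_maps, collapse = ", "),
                 paste(reg$name[reg$source_map %in% missing_maps],
                       collapse = ", ")))
  if (!all(c("T1CE", "T2FLAIR") %in% names(rois)))
    stop("rois must contain T1CE and T2FLAIR masks")
  adc_valid <- attr(maps$rADC, "valid")
  if (is.null(adc_valid)) adc_valid <- is.finite(maps$rADC)

  out <- stats::setNames(numeric(nrow(reg)), reg$name)
  vf <- lapply(rois, volume_features)
  hf <- list()  # cached per (map, basis) family
  for (i in seq_len(nrow(reg))) {
    s <- reg[i, ]
    roi <- rois[[s$roi_basis]]
    if (s$source_map %in% c("T1CE-mask", "T2FLAIR-mask")) {
      out[i] <- vf[[s$roi_basis]][[s$statistic]]
    } else if (s$statistic %in% c("pixel_count", "area_cm2", "volume_ml")) {
      vroi <- roi_mask(roi$voxels & adc_valid & is.finite(maps$rADC),
                       roi$basis, roi$spacing)
      out[i] <- volume_features(vroi)[[s$statistic]]
    } else {
      key <- paste(s$source_map, s$roi_basis)
      if (is.null(hf[[key]]))
        hf[[key]] <- histogram_features(maps[[s$source_map]], roi)
      out[i] <- hf[[key]][[s$statistic]]
    }
  }
  out
}
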