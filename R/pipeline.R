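## End-to-end orchestration: per-patient physiologic maps -> 82-feature
## matrix -> consensus subtypes -> transcriptomic signatures -> genomic and
## survival associations, with every output written beside a manifest so a
## run is reproducible from its seed and parameter snapshot.

#' Compute all physiologic maps and ROIs for one patient
#'
#' ADC from the DWI pair; rCBV/rCBF/MTT/TTP from the DSC series (leakage
#' corrected, gamma-variate fitted inside the FLAIR ROI and the normal
#' reference region); ADC, CBV and CBF normalized to the reference-region
#' median (the "r" maps); ROIs exclusion-subtracted.
#'
#' @param imaging a `patient_imaging` record (see [simulate_cohort]).
#' @param fit_method gamma-variate fit path for maps (default `"loglin"`).
#' @return List `maps` (`rADC`, `rCBF`, `rCBV`, `MTT`, `TTP`), `rois`
#'   (`T1CE`, `T2FLAIR`), `n_failed_fits`, `n_clamped_adc`.
#' @export
compute_patient_maps <- function(imaging, fit_method = "loglin") {
  stopifnot(inherits(imaging, "patient_imaging"))
  adc <- compute_adc(imaging$dwi_b0, imaging$dwi_b1000,
                     b = max(imaging$b_values))
  pm <- compute_perfusion_maps(imaging$dsc,
                               fit_mask = imaging$t2flair_mask,
                               reference_mask = imaging$reference_mask,
                               method = fit_method)
  ref <- imaging$reference_mask
  radc <- normalize_relative(adc, ref)
  attr(radc, "valid") <- attr(adc, "valid")
  maps <- list(rADC = radc,
               rCBF = normalize_relative(pm$rcbf, ref),
               rCBV = normalize_relative(pm$rcbv, ref),
               MTT = pm$mtt, TTP = pm$ttp)
  rois <- list(
    T1CE = subtract_exclusions(
      roi_mask(imaging$t1ce_mask, "T1CE", imaging$spacing),
      imaging$necrosis_mask, imaging$vessel_mask),
    T2FLAIR = subtract_exclusions(
      roi_mask(imaging$t2flair_mask, "T2FLAIR", imaging$spacing),
      imaging$necrosis_mask, imaging$vessel_mask))
  list(maps = maps, rois = rois, n_failed_fits = pm$n_failed,
       n_clamped_adc = attr(adc, "n_clamped"))
}

#' Extract the radiomic matrix for a whole cohort
#'
#' Runs [compute_patient_maps] and [extract_patient_features] per patient.
#'
#' @param cohort a [simulate_cohort] result (or any list with an `imaging`
#'   element of `patient_imaging` records).
#' @param fit_method passed to [compute_patient_maps].
#' @return Patients x 82 numeric matrix (registry column order), with
#'   attributes `n_failed_fits` and `n_clamped_adc` (per-patient counts).
#' @export
extract_cohort_features <- function(cohort, fit_method = "loglin") {
  imaging <- cohort$imaging
  reg <- feature_registry()
  out <- matrix(NA_real_, length(imaging), nrow(reg),
                dimnames = list(names(imaging), reg$name))
  failed <- clamped <- integer(length(imaging))
  for (i in seq_along(imaging)) {
    pm <- compute_patient_maps(imaging[[i]], fit_method = fit_method)
    out[i, ] <- extract_patient_features(pm$maps, pm$rois)
    failed[i] <- pm$n_failed_fits
    clamped[i] <- pm$n_clamped_adc
  }
  structure(out, n_failed_fits = failed, n_clamped_adc = clamped)
}

## default gene-set collection for the synthetic cohort: the planted marker
## pathways plus deterministic random sets as negative controls
.default_gene_sets <- function(cohort, n_random = 5, size = 50, seed = 9L) {
  sets <- cohort$truth$marker_genes
  names(sets) <- paste0("pathway_", names(sets), "_markers")
  genes <- rownames(cohort$expression)
  set.seed(seed)
  for (i in seq_len(n_random))
    sets[[sprintf("pathway_random_%02d", i)]] <- sample(genes, size)
  sets
}

.write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(rn = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(x)[1] <- rownames_as
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a cohort's imaging as NIfTI plus TSV tables
#'
#' One NIfTI file per modality per patient (4D for the DSC series), masks
#' as integer-labelled NIfTI, and the expression/mutation/CNV/survival and
#' ground-truth tables as TSV.
#'
#' @param cohort a [simulate_cohort] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- cohort$config$voxel_spacing
  files <- character()
  tr <- cohort$config$dsc_params$tr
  wn <- function(img, path) {
    nii <- RNifti::asNifti(img)
    RNifti::pixdim(nii) <- if (length(dim(img)) == 4) c(sp, tr) else sp
    RNifti::writeNifti(nii, path)
    path
  }
  for (id in names(cohort$imaging)) {
    im <- cohort$imaging[[id]]
    pdir <- file.path(dir, id)
    dir.create(pdir, showWarnings = FALSE)
    files <- c(files,
      wn(im$t1ce, file.path(pdir, "t1ce.nii.gz")),
      wn(im$t2flair, file.path(pdir, "t2flair.nii.gz")),
      wn(im$dwi_b0, file.path(pdir, "dwi_b0.nii.gz")),
      wn(im$dwi_b1000, file.path(pdir, "dwi_b1000.nii.gz")),
      wn(aperm(im$dsc$data, c(2, 3, 4, 1)), file.path(pdir, "dsc.nii.gz")),
      wn(1L * im$t1ce_mask + 2L * im$t2flair_mask + 4L * im$necrosis_mask +
           8L * im$vessel_mask + 16L * im$reference_mask,
         file.path(pdir, "masks.nii.gz")))
  }
  files <- c(files,
    .write_tsv(cohort$expression, file.path(dir, "expression.tsv"), "gene"),
    .write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"), "gene"),
    .write_tsv(cohort$cnv, file.path(dir, "cnv.tsv"), "gene"),
    .write_tsv(cohort$survival, file.path(dir, "survival.tsv")),
    .write_tsv(data.frame(patient_id = names(cohort$truth$subtype_labels),
                          subtype = unname(cohort$truth$subtype_labels)),
               file.path(dir, "ground_truth.tsv")))
  invisible(files)
}

#' Run the full radiogenomic pipeline
#'
#' simulate -> maps -> radiomics -> subtyping -> signatures -> association
#' -> survival, writing every table to `outdir` and recording files,
#' checksums, seed and parameters in a manifest. All randomness flows from
#' `config$seed`.
#'
#' @param config a [cohort_config] (its seed drives every stage).
#' @param outdir output directory.
#' @param cohort optionally, a pre-simulated cohort (skips simulation; must
#'   be supplied if the simulate stage is disabled).
#' @param stages character subset of
#'   `c("simulate","maps","cluster","signatures","associate","survival")`;
#'   later stages require the earlier ones.
#' @param k_range,n_resamples,subsample_fraction consensus-clustering
#'   parameters.
#' @param candidate_sizes,n_folds signature-size cross-validation grid.
#' @param ssgsea_alpha rank-weight exponent for [ssgsea].
#' @param rho_min,p_max,adj_p_max screening thresholds (defaults 0.6,
#'   0.05, 0.01).
#' @param gene_sets named list of gene sets; defaults to the planted marker
#'   pathways plus random control sets.
#' @param fit_method gamma-variate fit path for maps.
#' @param write_images also write per-patient NIfTI volumes.
#' @return Object of class `pipeline_result` with all stage outputs and a
#'   `manifest` (seed, parameters, files with md5 checksums).
#' @export
run_pipeline <- function(config = cohort_config(), outdir,
                         cohort = NULL,
                         stages = c("simulate", "maps", "cluster",
                                    "signatures", "associate", "survival"),
                         k_range = 2:6, n_resamples = 500,
                         subsample_fraction = 0.8,
                         candidate_sizes = c(5, 10, 25, 50), n_folds = 5,
                         ssgsea_alpha = 0.25,
                         rho_min = 0.6, p_max = 0.05, adj_p_max = 0.01,
                         gene_sets = NULL, fit_method = "loglin",
                         write_images = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  check_scalar_num(rho_min, "rho_min", 0, 1)
  check_scalar_num(p_max, "p_max", 0, 1, strict_lower = TRUE)
  check_scalar_num(adj_p_max, "adj_p_max", 0, 1, strict_lower = TRUE)
  # validate stage wiring before any compute
  if (is.null(cohort) && !"simulate" %in% stages)
    stop("validation error: simulate stage disabled but no cohort supplied")
  if ("signatures" %in% stages && !"cluster" %in% stages)
    stop("validation error: signatures stage requires the cluster stage")
  if (("cluster" %in% stages || "associate" %in% stages) && !"maps" %in% stages)
    stop("validation error: cluster/associate stages require the maps stage")
  if (!is.null(cohort) && "signatures" %in% stages && is.null(cohort$expression))
    stop("validation error: signatures stage enabled but cohort has no expression matrix")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(manifest = list(seed = config$seed,
                              parameters = list(
                                k_range = k_range, n_resamples = n_resamples,
                                subsample_fraction = subsample_fraction,
                                candidate_sizes = candidate_sizes,
                                n_folds = n_folds, ssgsea_alpha = ssgsea_alpha,
                                rho_min = rho_min, p_max = p_max,
                                adj_p_max = adj_p_max,
                                fit_method = fit_method),
                              files = character()))
  add_file <- function(p) res$manifest$files <<- c(res$manifest$files, p)

  if ("simulate" %in% stages && is.null(cohort))
    cohort <- simulate_cohort(config)
  res$cohort <- cohort
  if (write_images) write_cohort(cohort, file.path(outdir, "images"))

  if ("maps" %in% stages) {
    res$features <- extract_cohort_features(cohort, fit_method = fit_method)
    add_file(.write_tsv(res$features, file.path(outdir, "radiomic_matrix.tsv"),
                        "patient_id"))
  }
  if ("cluster" %in% stages) {
    res$standardized <- standardize(res$features)
    res$consensus <- consensus_cluster(
      res$standardized, k_range = k_range, n_resamples = n_resamples,
      subsample_fraction = subsample_fraction,
      seed = child_seed(config$seed, 200001L))
    res$clusters <- cluster_assignments(res$consensus)
    add_file(.write_tsv(
      data.frame(patient_id = names(res$clusters),
                 cluster = unname(res$clusters),
                 true_subtype = unname(cohort$truth$subtype_labels)),
      file.path(outdir, "clusters.tsv")))
    add_file(.write_tsv(
      data.frame(k = res$consensus$k_range,
                 pac = unname(res$consensus$stability_curve)),
      file.path(outdir, "stability.tsv")))
    add_file(.write_tsv(res$consensus$consensus[[as.character(res$consensus$k_selected)]],
                        file.path(outdir, "consensus_matrix.tsv"), "patient_id"))
  }
  if ("signatures" %in% stages) {
    expr <- cohort$expression
    if (is.null(expr))
      stop("validation error: signatures stage enabled but cohort has no expression matrix")
    if (is.null(gene_sets)) gene_sets <- .default_gene_sets(cohort)
    res$gene_sets <- gene_sets
    cl_lab <- paste0("cluster", res$clusters)
    res$clanc_cv <- clanc_cv(expr, cl_lab, candidate_sizes,
                             n_folds = n_folds,
                             seed = child_seed(config$seed, 200002L))
    res$clanc <- clanc_train(expr, cl_lab, res$clanc_cv$chosen)
    res$ssgsea_scores <- ssgsea(expr, gene_sets, alpha = ssgsea_alpha)
    add_file(.write_tsv(res$ssgsea_scores,
                        file.path(outdir, "ssgsea_scores.tsv"), "pathway"))
    add_file(.write_tsv(
      data.frame(class = rep(names(res$clanc$selected_genes),
                             each = res$clanc$genes_per_class),
                 gene = unlist(res$clanc$selected_genes, use.names = FALSE)),
      file.path(outdir, "clanc_signature.tsv")))
  }
  if ("associate" %in% stages) {
    expr <- cohort$expression
    res$pathway_screen <- spearman_screen(res$features, res$ssgsea_scores,
                                          rho_min = rho_min, p_max = p_max)
    res$gene_screen <- spearman_screen(res$features, expr,
                                       rho_min = rho_min, p_max = p_max)
    screen_genes <- unique(res$gene_screen$genomic_entity)
    res$ora <- ora_screen(screen_genes, res$gene_sets, rownames(expr))
    res$mutation_screen <- variant_effect_screen(res$features, cohort$mutations)
    res$cnv_screen <- variant_effect_screen(res$features, cohort$cnv)
    add_file(.write_tsv(res$pathway_screen,
                        file.path(outdir, "pathway_associations.tsv")))
    add_file(.write_tsv(res$ora, file.path(outdir, "ora_enrichment.tsv")))
    add_file(.write_tsv(res$mutation_screen,
                        file.path(outdir, "mutation_associations.tsv")))
    add_file(.write_tsv(res$cnv_screen,
                        file.path(outdir, "cnv_associations.tsv")))
  }
  if ("survival" %in% stages) {
    surv <- cohort$survival
    if ("cluster" %in% stages)
      surv$group <- paste0("cluster", res$clusters[surv$patient_id])
    res$km <- km_logrank(surv)
    add_file(.write_tsv(res$km$summary,
                        file.path(outdir, "survival_summary.tsv")))
  }
  res$manifest$files <- stats::setNames(
    as.character(tools::md5sum(res$manifest$files)),
    basename(res$manifest$files))
  .write_tsv(data.frame(file = names(res$manifest$files),
                        md5 = unname(res$manifest$files)),
             file.path(outdir, "manifest.tsv"))
  res$outdir <- outdir
  class(res) <- "pipeline_result"
  res
}

#' Human-readable summary of a pipeline run
#'
#' Cluster sizes and selected k, significant pathway enrichments at the
#' adjusted-p threshold, and per-cluster survival medians; stages whose
#' outputs are missing are listed and the rest still reported. The text is
#' deterministic, so regeneration from the same run is byte-identical.
#'
#' @param result a [run_pipeline] result.
#' @param adj_p_max significance threshold for reported associations
#'   (default 0.01).
#' @param file optional path to also write the report to.
#' @return Character vector of report lines, invisibly if `file` is given.
#' @export
pipeline_report <- function(result, adj_p_max = 0.01, file = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  lines <- c("Radiomic phenotyping pipeline report",
             sprintf("seed: %d", result$manifest$seed))
  missing_stages <- character()
  if (!is.null(result$consensus)) {
    lines <- c(lines,
      sprintf("selected cluster number k = %d (PAC: %s)",
              result$consensus$k_selected,
              paste(sprintf("k%s=%.3f", result$consensus$k_range,
                            result$consensus$stability_curve), collapse = ", ")),
      sprintf("cluster sizes: %s",
              paste(sprintf("%s=%d", names(table(result$clusters)),
                            as.integer(table(result$clusters))), collapse = ", ")))
  } else missing_stages <- c(missing_stages, "cluster")
  if (!is.null(result$ora)) {
    sig <- result$ora[result$ora$adjusted_p <= adj_p_max, , drop = FALSE]
    lines <- c(lines,
      if (nrow(sig) == 0) "0 significant pathway enrichments"
      else c(sprintf("%d significant pathway enrichment(s) at adjusted p <= %g:",
                     nrow(sig), adj_p_max),
             sprintf("  %s (overlap %d/%d, OR %.2f, adj p %.3g)",
                     sig$set_name, sig$overlap, sig$set_size,
                     sig$odds_ratio, sig$adjusted_p)))
    npw <- if (is.null(result$pathway_screen)) 0L else nrow(result$pathway_screen)
    lines <- c(lines, sprintf(
      "%d radiomic-pathway association(s) passed the Spearman screen", npw))
  } else missing_stages <- c(missing_stages, "associate")
  if (!is.null(result$km)) {
    s <- result$km$summary
    lines <- c(lines, "survival by cluster (median months [95% CI]):",
               sprintf("  %s: %.1f [%.1f, %.1f], %d/%d events",
                       s$group, s$median, s$lcl, s$ucl, s$events, s$n),
               sprintf("log-rank p = %.4g", result$km$p))
  } else missing_stages <- c(missing_stages, "survival")
  if (length(missing_stages))
    lines <- c(lines, sprintf("missing stage output(s): %s",
                              paste(missing_stages, collapse = ", ")))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
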