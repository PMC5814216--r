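## Imaging-subtype discovery: z-standardization of the radiomic matrix and
## consensus clustering over patient subsamples with average-linkage
## agglomeration on 1 - Pearson correlation, with the cluster number chosen
## by the proportion of ambiguous clustering (PAC).

#' Z-standardize a feature matrix
#'
#' Centers and scales every feature column to mean 0 and unit SD (n-1).
#' Constant columns carry no clustering information and are dropped with a
#' warning naming them.
#'
#' @param x patients x features numeric matrix.
#' @return Standardized matrix (possibly fewer columns).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 patients")
  sds <- apply(x, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (all(const)) stop("all feature columns are constant")
  if (any(const)) {
    warning(sprintf("dropping %d constant column(s): %s", sum(const),
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Patient-by-patient Pearson similarity
#'
#' Entry (i, j) is the Pearson correlation of the two patients' feature
#' vectors; symmetric with unit diagonal.
#'
#' @param x patients x features matrix (>= 2 features).
#' @return Patients x patients correlation matrix.
#' @export
pearson_similarity <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features per patient")
  rv <- apply(x, 1, stats::sd)
  if (any(rv == 0)) {
    bad <- rownames(x)[rv == 0]
    if (is.null(bad)) bad <- which(rv == 0)
    stop(sprintf("zero-variance patient vector(s): %s",
                 paste(bad, collapse = ", ")))
  }
  s <- stats::cor(t(x))
  diag(s) <- 1
  s
}

.pac <- function(consensus, lower = 0.1, upper = 0.9) {
  v <- consensus[upper.tri(consensus)]
  mean(v > lower & v < upper)
}

#' Consensus clustering of patients
#'
#' Repeatedly subsamples patients, clusters each subsample by
#' average-linkage agglomeration on distance 1 - Pearson similarity, and
#' accumulates co-clustering frequencies into one consensus matrix per
#' candidate k. Final assignments at each k come from clustering the
#' consensus matrix itself; the cluster number is selected by minimal PAC.
#'
#' @param x patients x features matrix (standardized; see [standardize]).
#' @param k_range candidate cluster counts, within `[2, n - 1]`.
#' @param n_resamples number of subsampling iterations (default 500).
#' @param subsample_fraction fraction of patients per resample, in
#'   `(0.5, 1]` (default 0.8).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param pac_bounds lower/upper consensus thresholds for PAC
#'   (default `c(0.1, 0.9)`).
#' @return Object of class `consensus_result`: `consensus` (list of
#'   patient x patient matrices, one per k), `assignments` (matrix, one
#'   column per k), `stability_curve` (PAC per k), `k_selected`, `seed`.
#' @export
consensus_cluster <- function(x, k_range = 2:6, n_resamples = 500,
                              subsample_fraction = 0.8, seed = 1L,
                              pac_bounds = c(0.1, 0.9)) {
  x <- as.matrix(x)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n_patients - 1]")
  check_scalar_num(subsample_fraction, "subsample_fraction", 0.5, 1,
                   strict_lower = TRUE)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  m <- max(2L, as.integer(ceiling(subsample_fraction * n)))
  set.seed(seed)
  co <- lapply(k_range, function(k) matrix(0, n, n))
  names(co) <- as.character(k_range)
  nsamp <- matrix(0, n, n)
  for (r in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, m))
    nsamp[idx, idx] <- nsamp[idx, idx] + 1
    d <- stats::as.dist(1 - pearson_similarity(x[idx, , drop = FALSE]))
    hc <- stats::hclust(d, method = "average")
    for (k in k_range) {
      cl <- stats::cutree(hc, k = k)
      same <- outer(cl, cl, "==")
      ck <- co[[as.character(k)]]
      ck[idx, idx] <- ck[idx, idx] + same
      co[[as.character(k)]] <- ck
    }
  }
  consensus <- lapply(co, function(ck) {
    cm <- ifelse(nsamp > 0, ck / nsamp, 0)
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    cm
  })
  assignments <- sapply(k_range, function(k) {
    cm <- consensus[[as.character(k)]]
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    stats::cutree(hc, k = k)
  })
  dimnames(assignments) <- list(ids, as.character(k_range))
  pac <- vapply(consensus, .pac, 0, lower = pac_bounds[1], upper = pac_bounds[2])
  res <- structure(list(consensus = consensus, assignments = assignments,
                        stability_curve = stats::setNames(pac, names(consensus)),
                        k_range = k_range, seed = seed),
                   class = "consensus_result")
  res$k_selected <- select_k(res)
  res
}

#' Select the cluster number from a consensus result
#'
#' Returns the candidate k with the lowest proportion of ambiguous
#' clustering (consensus entries strictly between the PAC bounds); ties go
#' to the smallest k.
#'
#' @param result a [consensus_cluster] result.
#' @return Integer k.
#' @export
select_k <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  pac <- result$stability_curve
  result$k_range[which(pac <= min(pac) + 1e-12)[1]]
}

#' Cluster assignment at the selected (or a given) k
#'
#' @param result a [consensus_cluster] result.
#' @param k cluster count (default the selected one).
#' @return Named integer vector of cluster labels.
#' @export
cluster_assignments <- function(result, k = result$k_selected) {
  stopifnot(inherits(result, "consensus_result"))
  kk <- as.character(k)
  if (!kk %in% colnames(result$assignments))
    stop(sprintf("k = %s was not among the candidates", kk))
  result$assignments[, kk]
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus clustering over k in {%s}; selected k = %d\n",
              paste(x$k_range, collapse = ", "), x$k_selected))
  cat("PAC per k:\n")
  print(round(x$stability_curve, 4))
  cat("cluster sizes at selected k:\n")
  print(table(cluster_assignments(x)))
  invisible(x)
}

#' @param x a `consensus_result`.
#' @param k which consensus matrix to draw (default the selected k).
#' @param ... passed to [graphics::image].
#' @describeIn consensus_cluster heatmap of the consensus matrix with
#'   patients ordered by cluster.
#' @export
plot.consensus_result <- function(x, k = x$k_selected, ...) {
  cm <- x$consensus[[as.character(k)]]
  ord <- order(x$assignments[, as.character(k)])
  graphics::image(cm[ord, rev(ord)], axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  main = sprintf("consensus matrix, k = %s", k), ...)
  invisible(x)
}
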