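## Radiomic-genomic and radiomic-outcome association statistics:
## tie-aware Spearman screening, Mann-Whitney group tests, per-gene
## mutation/CNV regression, BH adjustment, and Kaplan-Meier/log-rank
## comparison of patient clusters.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1,
#' input order preserved.
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## tie-aware Spearman rho with two-sided t-approximation p-value
.spearman <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (!is.finite(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Spearman screen of radiomic features against genomic entities
#'
#' Computes the tie-aware (midrank) Spearman correlation of every
#' (feature, entity) pair with a two-sided t-approximation p-value, then
#' BH-adjusts over all computed pairs and keeps those passing
#' `|rho| > rho_min` and `p < p_max`. Pairs with a constant vector on
#' either side are skipped and counted.
#'
#' @param radiomic patients x features matrix with patient rownames.
#' @param genomic entities x patients matrix (genes or pathway scores)
#'   with patient colnames.
#' @param rho_min absolute correlation threshold (default 0.6).
#' @param p_max p-value threshold (default 0.05).
#' @return `data.frame` with `radiomic_feature`, `genomic_entity`, `rho`,
#'   `p_value`, `adjusted_p`, `n_used`; attribute `n_skipped` counts
#'   constant pairs, `n_tested` all computed pairs.
#' @export
spearman_screen <- function(radiomic, genomic, rho_min = 0.6, p_max = 0.05) {
  radiomic <- as.matrix(radiomic)
  genomic <- as.matrix(genomic)
  pts <- intersect(rownames(radiomic), colnames(genomic))
  if (length(pts) < 5) stop("need at least 5 shared patients")
  R <- radiomic[pts, , drop = FALSE]
  G <- genomic[, pts, drop = FALSE]
  # rank once per vector; constant vectors flagged by zero variance
  feats <- colnames(R); ents <- rownames(G)
  n <- length(pts)
  skipped <- 0L
  rows <- vector("list", length(feats) * length(ents))
  ri <- 0L
  for (f in seq_along(feats)) {
    xf <- R[, f]
    if (stats::sd(xf) == 0) { skipped <- skipped + length(ents); next }
    for (g in seq_along(ents)) {
      yg <- G[g, ]
      if (stats::sd(yg) == 0) { skipped <- skipped + 1L; next }
      sp <- .spearman(xf, yg)
      ri <- ri + 1L
      rows[[ri]] <- c(f = f, g = g, rho = sp[["rho"]], p = sp[["p"]])
    }
  }
  if (ri == 0L) {
    out <- data.frame(radiomic_feature = character(), genomic_entity = character(),
                      rho = numeric(), p_value = numeric(),
                      adjusted_p = numeric(), n_used = integer())
    attr(out, "n_skipped") <- skipped; attr(out, "n_tested") <- 0L
    return(out)
  }
  m <- do.call(rbind, rows[seq_len(ri)])
  adj <- bh_adjust(m[, "p"])
  keep <- abs(m[, "rho"]) > rho_min & m[, "p"] < p_max
  out <- data.frame(radiomic_feature = feats[m[keep, "f"]],
                    genomic_entity = ents[m[keep, "g"]],
                    rho = m[keep, "rho"], p_value = m[keep, "p"],
                    adjusted_p = adj[keep], n_used = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- skipped
  attr(out, "n_tested") <- ri
  out
}

#' Mann-Whitney U test between two patient groups
#'
#' Two-sided test; exact by enumeration when the combined sample is small
#' (n <= 12) and tie-free, otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param values numeric vector (named if ids are names).
#' @param group_a,group_b indices or names into `values`.
#' @return List `U` (statistic for group A) and `p`.
#' @export
mannwhitney_test <- function(values, group_a, group_b) {
  xa <- values[group_a]; xb <- values[group_b]
  if (length(xa) == 0 || length(xb) == 0) stop("empty group")
  if (length(xa) + length(xb) < 4) stop("need a combined sample of at least 4")
  n <- length(xa) + length(xb)
  has_ties <- anyDuplicated(c(xa, xb)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    xa, xb, exact = (n <= 12 && !has_ties), correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Per-gene effect of a mutation or copy-number dosage on a phenotype
#'
#' Ordinary least squares of the radiomic phenotype on an intercept plus
#' the variant indicator/dosage, with a two-sided t-test on the slope. A
#' constant indicator, or a binary indicator with fewer than `min_variant_n`
#' carriers, is reported as untestable rather than raising an error (small
#' mutation counts do not support reliable statistics).
#'
#' @param phenotype numeric feature values.
#' @param indicator 0/1 mutation presence or continuous CNV dosage.
#' @param min_variant_n minimum carriers for a binary indicator (default 3).
#' @return List `coefficient`, `se`, `p`, `testable`, `n_used`.
#' @export
variant_effect_regression <- function(phenotype, indicator, min_variant_n = 3) {
  ok <- is.finite(phenotype) & is.finite(indicator)
  y <- phenotype[ok]; z <- indicator[ok]
  n <- length(y)
  untestable <- function() list(coefficient = NA_real_, se = NA_real_,
                                p = NA_real_, testable = FALSE, n_used = n)
  if (n < 4) return(untestable())
  uz <- unique(z)
  if (length(uz) < 2) return(untestable())
  if (length(uz) == 2 && all(uz %in% c(0, 1)) && sum(z == 1) < min_variant_n)
    return(untestable())
  fit <- stats::lm(y ~ z)
  cf <- summary(fit)$coefficients
  list(coefficient = cf["z", "Estimate"], se = cf["z", "Std. Error"],
       p = cf["z", "Pr(>|t|)"], testable = TRUE, n_used = n)
}

#' Screen radiomic features against a variant matrix
#'
#' Runs [variant_effect_regression] for every (feature, gene) pair and
#' BH-adjusts the testable p-values within the screen.
#'
#' @param radiomic patients x features matrix with patient rownames.
#' @param variants genes x patients mutation (0/1) or CNV (log2) matrix.
#' @param min_variant_n see [variant_effect_regression].
#' @return `data.frame` with `radiomic_feature`, `genomic_entity`,
#'   `coefficient`, `se`, `p_value`, `adjusted_p`, `n_used`, `testable`.
#' @export
variant_effect_screen <- function(radiomic, variants, min_variant_n = 3) {
  radiomic <- as.matrix(radiomic)
  variants <- as.matrix(variants)
  pts <- intersect(rownames(radiomic), colnames(variants))
  if (length(pts) < 4) stop("need at least 4 shared patients")
  R <- radiomic[pts, , drop = FALSE]
  V <- variants[, pts, drop = FALSE]
  grid <- expand.grid(f = colnames(R), g = rownames(V),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    variant_effect_regression(R[, grid$f[i]], V[grid$g[i], ], min_variant_n)
  })
  out <- data.frame(radiomic_feature = grid$f, genomic_entity = grid$g,
                    coefficient = vapply(res, `[[`, 0, "coefficient"),
                    se = vapply(res, `[[`, 0, "se"),
                    p_value = vapply(res, `[[`, 0, "p"),
                    n_used = vapply(res, `[[`, 0L, "n_used"),
                    testable = vapply(res, `[[`, TRUE, "testable"),
                    stringsAsFactors = FALSE)
  out$adjusted_p <- NA_real_
  out$adjusted_p[out$testable] <- bh_adjust(out$p_value[out$testable])
  out
}

#' Kaplan-Meier summary and log-rank test across patient groups
#'
#' Per-group KM median survival with Greenwood-based 95% confidence
#' intervals, and the k-group log-rank chi-square when more than one group
#' is present.
#'
#' @param survival_table `data.frame` with columns `time` (months),
#'   `event` (logical/0-1), `group`.
#' @return Object of class `km_logrank`: `summary` data.frame (group, n,
#'   events, median, lcl, ucl), `chisq`, `df`, `p` (NA for one group).
#' @export
km_logrank <- function(survival_table) {
  st <- survival_table
  if (!all(c("time", "event", "group") %in% names(st)))
    stop("survival table needs columns time, event, group")
  if (any(st$time <= 0)) stop("survival times must be positive")
  if (sum(st$event) == 0) stop("no events in survival table")
  st$group <- as.factor(st$group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = st)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- t(as.matrix(tab))  # single group
  groups <- levels(st$group)
  smry <- data.frame(group = groups,
                     n = tab[, "records"], events = tab[, "events"],
                     median = tab[, "median"],
                     lcl = tab[, "0.95LCL"], ucl = tab[, "0.95UCL"],
                     row.names = NULL, stringsAsFactors = FALSE)
  chisq <- df <- p <- NA_real_
  if (length(groups) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = st)
    chisq <- sd$chisq
    df <- length(groups) - 1
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  structure(list(summary = smry, chisq = chisq, df = df, p = p, fit = fit),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  if (is.finite(x$chisq))
    cat(sprintf("log-rank chi-square %.3f on %d df, p = %.4g\n",
                x$chisq, x$df, x$p))
  invisible(x)
}

#' @param x a `km_logrank` object.
#' @param ... passed to `plot.survfit`.
#' @describeIn km_logrank Kaplan-Meier curves per group.
#' @export
plot.km_logrank <- function(x, ...) {
  plot(x$fit, col = seq_len(nrow(x$summary)), xlab = "months",
       ylab = "survival", ...)
  graphics::legend("topright", legend = x$summary$group,
                   col = seq_len(nrow(x$summary)), lty = 1, bty = "n")
  invisible(x)
}
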