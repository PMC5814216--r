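## Transcriptomic machinery: RPKM + log2 transform, balanced
## nearest-centroid (ClaNC-style) signature genes with cross-validated
## size, single-sample GSEA scores, and Fisher-exact over-representation.

#' Reads-per-kilobase-per-million normalization
#'
#' RPKM[g, s] = 1e9 * counts[g, s] / (length[g] * library_size[s]).
#'
#' @param counts genes x patients non-negative count matrix.
#' @param gene_lengths transcript lengths (nt), one per gene row.
#' @param library_sizes mapped reads per patient column.
#' @return Genes x patients matrix with attribute `transform_tag = "raw"`.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (length(gene_lengths) != nrow(counts) ||
      length(library_sizes) != ncol(counts))
    stop("dimension mismatch between counts, lengths and library sizes")
  out <- 1e9 * counts / outer(gene_lengths, library_sizes)
  structure(out, transform_tag = "raw")
}

#' Log2(x + 1) transform of an expression matrix
#'
#' Corrects the skewed RPKM distribution; refuses to transform a matrix
#' already tagged as log-scale.
#'
#' @param expr non-negative matrix, optionally tagged `"raw"`.
#' @return Matrix with attribute `transform_tag = "log"`.
#' @export
log_transform <- function(expr) {
  if (identical(attr(expr, "transform_tag"), "log"))
    stop("matrix is already log-transformed")
  if (any(expr < 0)) stop("expression values must be non-negative")
  structure(log2(expr + 1), transform_tag = "log",
            dim = dim(expr), dimnames = dimnames(expr))
}

## per-gene per-class shrunken contrast statistic and pooled SD
.clanc_stats <- function(x, labels, classes) {
  n <- ncol(x)
  overall <- rowMeans(x)
  cmeans <- sapply(classes, function(cl) rowMeans(x[, labels == cl, drop = FALSE]))
  ss <- rowSums(sapply(classes, function(cl) {
    xc <- x[, labels == cl, drop = FALSE]
    rowSums((xc - rowMeans(xc))^2)
  }))
  pooled_sd <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(pooled_sd)
  d <- sapply(classes, function(cl) {
    nc <- sum(labels == cl)
    mc <- sqrt(1 / nc - 1 / n)
    (cmeans[, cl] - overall) / (mc * (pooled_sd + s0))
  })
  list(d = d, centroids = cmeans, pooled_sd = pooled_sd, s0 = s0)
}

#' Train a balanced nearest-centroid classifier
#'
#' ClaNC-style signature selection: per gene g and class c the statistic
#' d[g, c] = (mean_c - overall mean) / (m_c * (pooled SD + s0)) with
#' m_c = sqrt(1/n_c - 1/n) and shrinkage offset s0 = median pooled SD.
#' Genes are assigned greedily to classes in decreasing |d| under an exact
#' per-class quota, no gene serving two classes; class centroids are stored
#' over the union of selected genes.
#'
#' @param expr genes x patients log-scale matrix with rownames.
#' @param labels per-patient class labels (>= 2 classes, each >= 2 samples).
#' @param genes_per_class signature size quota per class.
#' @return Object of class `clanc_model`: `classes`, `selected_genes`
#'   (per-class, exactly the quota, pairwise disjoint), `centroids`,
#'   `pooled_sd`, `s0`, `genes_per_class`.
#' @export
clanc_train <- function(expr, labels, genes_per_class) {
  x <- as.matrix(expr)
  if (is.null(rownames(x))) stop("expr needs gene rownames")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  if (genes_per_class * length(classes) > nrow(x))
    stop("quota unsatisfiable: not enough genes for the per-class quota")
  st <- .clanc_stats(x, as.character(labels), classes)
  ord <- order(abs(st$d), decreasing = TRUE)
  gi <- ((ord - 1) %% nrow(x)) + 1
  ci <- ((ord - 1) %/% nrow(x)) + 1
  sel <- stats::setNames(vector("list", length(classes)), classes)
  taken <- logical(nrow(x))
  quota <- rep(genes_per_class, length(classes))
  for (r in seq_along(ord)) {
    g <- gi[r]; cl <- ci[r]
    if (taken[g] || quota[cl] == 0) next
    sel[[cl]] <- c(sel[[cl]], rownames(x)[g])
    taken[g] <- TRUE
    quota[cl] <- quota[cl] - 1
    if (all(quota == 0)) break
  }
  if (any(quota > 0)) stop("quota unsatisfiable: ran out of genes")
  union_genes <- unlist(sel, use.names = FALSE)
  structure(list(classes = classes, selected_genes = sel,
                 centroids = st$centroids[union_genes, , drop = FALSE],
                 pooled_sd = st$pooled_sd[union_genes], s0 = st$s0,
                 genes_per_class = genes_per_class),
            class = "clanc_model")
}

#' @export
print.clanc_model <- function(x, ...) {
  cat(sprintf("balanced nearest-centroid model: %d classes x %d genes each (s0 = %.3g)\n",
              length(x$classes), x$genes_per_class, x$s0))
  invisible(x)
}

#' Predict classes with a balanced nearest-centroid model
#'
#' Each sample is assigned the class minimizing the standardized squared
#' distance to that class's centroid over its own selected genes; exact
#' ties go to the first class in model order.
#'
#' @param object a [clanc_train] model.
#' @param expr genes x patients matrix containing all model genes.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.clanc_model <- function(object, expr, ...) {
  x <- as.matrix(expr)
  need <- rownames(object$centroids)
  miss <- setdiff(need, rownames(x))
  if (length(miss))
    stop(sprintf("model genes missing from expression matrix: %s",
                 paste(miss, collapse = ", ")))
  dist_c <- sapply(object$classes, function(cl) {
    g <- object$selected_genes[[cl]]
    z <- (x[g, , drop = FALSE] - object$centroids[g, cl]) /
      (object$pooled_sd[g] + object$s0)
    colSums(z^2)
  })
  if (is.null(dim(dist_c))) dist_c <- matrix(dist_c, nrow = 1)
  object$classes[apply(dist_c, 1, which.min)]
}

#' Cross-validated signature size for the balanced centroid classifier
#'
#' Stratified k-fold cross-validation of the misclassification rate over
#' candidate per-class signature sizes; the chosen size is the smallest one
#' attaining the minimum mean CV error.
#'
#' @param expr genes x patients log-scale matrix.
#' @param labels per-patient class labels.
#' @param candidate_sizes vector of per-class quotas to try.
#' @param n_folds folds (default 5); every class must have at least
#'   `n_folds` samples so each fold sees every class.
#' @param seed RNG seed for the fold split.
#' @return List `cv_curve` (data.frame `genes_per_class`, `cv_error`) and
#'   `chosen`.
#' @export
clanc_cv <- function(expr, labels, candidate_sizes, n_folds = 5, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < n_folds))
    stop("class too small to stratify over the requested folds")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  errs <- sapply(sort(candidate_sizes), function(l) {
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      model <- clanc_train(expr[, tr, drop = FALSE], labels[tr], l)
      pred <- predict(model, expr[, !tr, drop = FALSE])
      mean(pred != labels[!tr])
    }, 0))
  })
  curve <- data.frame(genes_per_class = sort(candidate_sizes), cv_error = errs)
  chosen <- curve$genes_per_class[which(errs <= min(errs) + 1e-12)[1]]
  list(cv_curve = curve, chosen = chosen)
}

## running-sum enrichment score for one sample's ordering
.ssgsea_sample <- function(ranked_genes, rank_weights, set) {
  inset <- ranked_genes %in% set
  w <- rank_weights * inset
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / sum(!inset)
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by expression (descending, ties broken
#' by gene id); the enrichment score is the sum over the ranked list of the
#' difference between the weighted in-set ECDF (weights rank^alpha,
#' normalized within the set) and the uniform out-of-set ECDF.
#'
#' @param expr genes x patients log-scale matrix with rownames.
#' @param sets named list of gene-id vectors (GMT semantics).
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize min-max rescale the whole score matrix to `[0, 1]`
#'   (default FALSE).
#' @return Sets x patients score matrix.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  x <- as.matrix(expr)
  genes <- rownames(x)
  if (is.null(genes)) stop("expr needs gene rownames")
  n <- length(genes)
  sets <- lapply(sets, function(s) intersect(s, genes))
  sizes <- lengths(sets)
  if (any(sizes == 0)) stop("gene set with no overlap with the matrix universe")
  if (any(sizes == n)) stop("gene set covering the whole universe")
  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    ord <- order(-x[, j], genes)
    ranked <- genes[ord]
    wts <- (n - seq_len(n) + 1)^alpha  # rank from bottom: top gene gets n^alpha
    for (s in seq_along(sets))
      scores[s, j] <- .ssgsea_sample(ranked, wts, sets[[s]])
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  scores
}

#' Fisher-exact over-representation of a gene list in a gene set
#'
#' One-sided hypergeometric tail probability of seeing at least the
#' observed overlap on the 2x2 in-list x in-set table over the universe;
#' the odds ratio uses a 0.5 continuity correction when any cell is zero.
#'
#' @param gene_list character vector (e.g. screened genes), subset of
#'   `universe`.
#' @param gene_set character vector, subset of `universe`.
#' @param universe all assayed gene ids (non-empty).
#' @return List `overlap`, `odds_ratio`, `p_value`.
#' @export
fisher_ora <- function(gene_list, gene_set, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  gl <- intersect(unique(gene_list), universe)
  gs <- intersect(unique(gene_set), universe)
  k <- length(intersect(gl, gs))
  N <- length(universe)
  a <- k
  b <- length(gl) - k
  cc <- length(gs) - k
  d <- N - length(gl) - length(gs) + k
  p <- stats::phyper(k - 1, length(gs), N - length(gs), length(gl),
                     lower.tail = FALSE)
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(overlap = k, odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       p_value = p)
}

#' Over-representation screen of a gene list against a collection
#'
#' Runs [fisher_ora] for every set and BH-adjusts the p-values across the
#' collection.
#'
#' @inheritParams fisher_ora
#' @param collection named list of gene sets.
#' @return `data.frame` with `set_name`, `overlap`, `set_size`,
#'   `odds_ratio`, `p_value`, `adjusted_p`.
#' @export
ora_screen <- function(gene_list, collection, universe) {
  rows <- lapply(names(collection), function(nm) {
    r <- fisher_ora(gene_list, collection[[nm]], universe)
    data.frame(set_name = nm, overlap = r$overlap,
               set_size = length(intersect(collection[[nm]], universe)),
               odds_ratio = r$odds_ratio, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then gene ids.
#'
#' @param path file path.
#' @return Named list of character vectors, with a `"description"`
#'   attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    structure(f[-(1:2)], description = f[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (optional per-set
#'   `"description"` attribute).
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
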