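#' @keywords internal
"_PACKAGE"

## small argument-checking helpers used across modules

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_cfg(name, "must be a finite numeric scalar")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_cfg(name, sprintf("must lie in %s%g, %g%s",
                           if (strict_lower) "(" else "[", lower, upper,
                           if (strict_upper) ")" else "]"))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to score recovery of planted subtypes by unsupervised clustering.
#'
#' @param a,b vectors of cluster labels (any atomic type), equal length.
#' @return A number; 1 for identical partitions (up to relabeling),
#'   around 0 for independent ones.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

## deterministic child seeds: spread one user seed over named streams
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}
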