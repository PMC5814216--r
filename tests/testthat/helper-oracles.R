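# independent oracles shared across test files

# small 3-class expression set with planted disjoint markers
planted_expression <- function(n_per_class = 10, l = 5, n_genes = 60,
                               effect = 4, seed = 15) {
  set.seed(seed)
  classes <- rep(c("A", "B", "C"), each = n_per_class)
  x <- matrix(rnorm(n_genes * length(classes)), n_genes, length(classes),
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_along(classes))))
  markers <- split(sprintf("g%02d", seq_len(3 * l)), rep(c("A", "B", "C"), each = l))
  for (cl in names(markers))
    x[markers[[cl]], classes == cl] <- x[markers[[cl]], classes == cl] + effect
  list(x = x, classes = classes, markers = markers)
}

# independent brute-force running sum for one sample
brute_ssgsea <- function(expr_col, genes, set, alpha) {
  ord <- order(-expr_col, genes)
  ranked <- genes[ord]
  n <- length(genes)
  p_in <- p_out <- 0
  w_all <- (n - seq_len(n) + 1)^alpha
  denom_in <- sum(w_all[ranked %in% set])
  denom_out <- sum(!(ranked %in% set))
  es <- 0
  for (i in seq_len(n)) {
    if (ranked[i] %in% set) p_in <- p_in + w_all[i] / denom_in
    else p_out <- p_out + 1 / denom_out
    es <- es + (p_in - p_out)
  }
  es
}
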