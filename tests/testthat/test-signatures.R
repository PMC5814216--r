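test_that("RPKM and log transform follow their formulas", {
  expect_equal(as.numeric(rpkm(matrix(1000), 2000, 1e7)), 50)
  expect_equal(as.numeric(rpkm(matrix(0), 500, 1e6)), 0)

  set.seed(14)
  cnt <- matrix(rpois(20, 40), 4, 5)
  len <- runif(4, 300, 3000); lib <- runif(5, 1e6, 5e7)
  r <- rpkm(cnt, len, lib)
  for (i in 1:4) for (j in 1:5)
    expect_equal(r[i, j], 1e9 * cnt[i, j] / (len[i] * lib[j]))
  expect_error(rpkm(matrix(-1), 100, 1e6), "negative")

  lt <- log_transform(r)
  expect_equal(as.numeric(lt), as.numeric(log2(r + 1)))
  expect_identical(attr(lt, "transform_tag"), "log")
  expect_error(log_transform(lt), "already")
  expect_equal(as.numeric(log_transform(matrix(c(0, 1, 7), 1))), c(0, 1, 3))
})

test_that("balanced centroid training fills exact disjoint quotas", {
  px <- planted_expression()
  m <- clanc_train(px$x, px$classes, genes_per_class = 5)
  expect_true(all(lengths(m$selected_genes) == 5))
  sel <- unlist(m$selected_genes)
  expect_false(anyDuplicated(sel) > 0)
  # planted recovery at large effect
  for (cl in c("A", "B", "C"))
    expect_setequal(m$selected_genes[[cl]], px$markers[[cl]])
  # separable data: zero training error
  expect_equal(predict(m, px$x), px$classes)

  expect_error(clanc_train(px$x, px$classes, genes_per_class = 30),
               "quota")
})

test_that("permuted labels reduce training accuracy to chance", {
  px <- planted_expression()
  set.seed(16)
  acc <- replicate(50, {
    perm <- sample(px$classes)
    m <- clanc_train(px$x, perm, genes_per_class = 5)
    mean(predict(m, px$x) == perm)
  })
  # overfitting inflates training accuracy above 1/3 even under the null;
  # the check is that it is far from separable-data accuracy and within a
  # few sigma of its own permutation distribution spread
  expect_lt(abs(mean(acc) - 1 / 3), 3 * sd(acc))
})

test_that("prediction uses standardized distance with first-class ties", {
  px <- planted_expression(effect = 6)
  m <- clanc_train(px$x, px$classes, genes_per_class = 5)
  # a class centroid embedded in a full-length profile is assigned its class
  probe <- matrix(0, nrow(px$x), 1, dimnames = list(rownames(px$x), "p"))
  probe[rownames(m$centroids), 1] <- m$centroids[, "B"]
  expect_equal(predict(m, probe), "B")

  # exactly equidistant input falls to the first class in model order
  sym <- planted_expression(n_per_class = 6, l = 2, n_genes = 10, effect = 3,
                            seed = 17)
  m2 <- clanc_train(sym$x, sym$classes, genes_per_class = 2)
  mid <- matrix(0, nrow(sym$x), 1, dimnames = list(rownames(sym$x), "m"))
  mid[rownames(m2$centroids), 1] <- rowMeans(m2$centroids)
  d <- sapply(m2$classes, function(cl) {
    g <- m2$selected_genes[[cl]]
    sum(((mid[g, 1] - m2$centroids[g, cl]) / (m2$pooled_sd[g] + m2$s0))^2)
  })
  if (max(d) - min(d) < 1e-12) expect_equal(predict(m2, mid), m2$classes[1])

  expect_error(predict(m, px$x[1:10, ]), "missing")
})

test_that("cross-validation picks the smallest size attaining minimal error", {
  px <- planted_expression(n_per_class = 15, l = 10, n_genes = 100, effect = 3,
                           seed = 18)
  cv <- clanc_cv(px$x, px$classes, candidate_sizes = c(2, 5, 10, 20),
                 n_folds = 5, seed = 9)
  expect_lte(cv$chosen, 10)
  expect_equal(min(cv$cv_curve$cv_error),
               cv$cv_curve$cv_error[cv$cv_curve$genes_per_class == cv$chosen])

  cv2 <- clanc_cv(px$x, px$classes, candidate_sizes = c(2, 5, 10, 20),
                  n_folds = 5, seed = 9)
  expect_identical(cv, cv2)

  single <- clanc_cv(px$x, px$classes, candidate_sizes = 7, seed = 1)
  expect_equal(single$chosen, 7)

  expect_error(clanc_cv(px$x[, 1:18], px$classes[1:18], 2, n_folds = 5),
               "stratify")
})

test_that("ssGSEA equals the hand-enumerated and brute-force running sums", {
  x <- matrix(c(5, 4, 3, 2, 1), 5, 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  expect_equal(as.numeric(ssgsea(x, list(top = c("g1", "g2")), alpha = 0)),
               2.5)
  expect_lt(as.numeric(ssgsea(x, list(bottom = c("g4", "g5")), alpha = 0)), 0)

  set.seed(19)
  xr <- matrix(rnorm(150), 50, 3,
               dimnames = list(sprintf("g%02d", 1:50), c("a", "b", "c")))
  sets <- list(s1 = sample(rownames(xr), 8), s2 = sample(rownames(xr), 20))
  sc <- ssgsea(xr, sets, alpha = 0.25)
  for (s in names(sets)) for (j in 1:3)
    expect_equal(sc[s, j],
                 brute_ssgsea(xr[, j], rownames(xr), sets[[s]], 0.25),
                 tolerance = 1e-12)

  # rank-based: invariant to any monotone per-sample transformation
  xm <- xr
  xm[, 1] <- exp(xm[, 1]); xm[, 2] <- 5 * xm[, 2] + 2; xm[, 3] <- xm[, 3]^3
  expect_equal(ssgsea(xm, sets, alpha = 0.25), sc, tolerance = 1e-10)

  expect_error(ssgsea(xr, list(all = rownames(xr))), "whole universe")
  expect_error(ssgsea(xr, list(none = c("zz1", "zz2"))), "no overlap")
})

test_that("over-representation p-values match hypergeometric enumeration", {
  uni <- sprintf("u%03d", 1:100)
  disjoint <- fisher_ora(uni[1:20], uni[21:30], uni)
  expect_equal(disjoint$p_value, 1)
  expect_equal(disjoint$overlap, 0)

  full <- fisher_ora(uni[1:20], uni[1:10], uni)
  # enumeration: P(overlap >= 10) with list 20, set 10, universe 100
  oracle <- sum(vapply(10:10, function(k)
    choose(10, k) * choose(90, 20 - k) / choose(100, 20), 0))
  expect_equal(full$p_value, oracle, tolerance = 1e-12)

  # doubling all cells of a positively associated table decreases p
  p1 <- fisher_ora(uni[1:20], uni[c(1:8, 95:96)], uni)$p_value
  uni2 <- sprintf("v%03d", 1:200)
  p2 <- fisher_ora(uni2[1:40], uni2[c(1:16, 189:192)], uni2)$p_value
  expect_lt(p2, p1)

  expect_error(fisher_ora("a", "b", character()), "empty universe")
})

test_that("ORA p-values are uniform under a permutation null", {
  # wide margins make the hypergeometric fine-grained enough for a KS check
  uni <- as.character(seq_len(10000))
  gs <- uni[seq_len(4000)]
  set.seed(22)
  p <- vapply(seq_len(2000), function(i)
    fisher_ora(uni[sample.int(10000, 2500)], gs, uni)$p_value, 0)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g4"))
  attr(sets$alpha, "description") <- "first set"
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(names(back), names(sets))
  expect_equal(as.character(back$alpha), as.character(sets$alpha))
  expect_equal(attr(back$alpha, "description"), "first set")
  expect_equal(as.character(back$beta), as.character(sets$beta))
})
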