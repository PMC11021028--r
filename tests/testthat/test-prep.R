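test_that("log2 + quantile normalization matches the hand-computed example", {
  counts <- matrix(c(1, 7, 3, 15), 2, 2)
  out <- log2_quantile_normalize(counts, offset = 1)
  expect_equal(unname(out), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))

  # identical columns are a fixed point
  x <- matrix(c(2, 5, 9, 2, 5, 9), 3, 2)
  expect_equal(unname(log2_quantile_normalize(x)), log2(x + 1),
               ignore_attr = TRUE)

  # definitional property: every column shares the reference distribution
  # (tie-free input; tied counts share averaged reference quantiles)
  set.seed(4)
  y <- matrix(rlnorm(200, 3, 0.7), 40, 5)
  norm <- log2_quantile_normalize(y)
  ref <- sort(norm[, 1])
  for (j in 2:5) expect_equal(sort(norm[, j]), ref)
  expect_error(log2_quantile_normalize(y[, 1, drop = FALSE]),
               class = "mppeqtl_invalid_argument")
})

test_that("response is signed copper minus control with strict pairing", {
  cu <- matrix(c(12, 3, 5, 5), 2, 2,
               dimnames = list(c("g1", "g2"), c("sA", "sB")))
  ct <- matrix(c(4, 10, 5, 5), 2, 2,
               dimnames = list(c("g1", "g2"), c("sA", "sB")))
  resp <- compute_response(cu, ct)
  expect_equal(resp["g1", "sA"], 8)    # copper-induced
  expect_equal(resp["g2", "sA"], -7)   # copper-repressed
  expect_true(all(resp[, "sB"] == 0))
  colnames(ct) <- c("sA", "sC")
  expect_error(compute_response(cu, ct), class = "mppeqtl_missing_pair")
  expect_error(compute_response(cu, ct), "sB")
})

test_that("signed normalization preserves sign structure and magnitudes", {
  set.seed(5)
  d <- matrix(rnorm(25, 0, 20), 5, 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  d[2, 3] <- 0
  out <- signed_normalize(d)
  expect_equal(sign(out), sign(d))
  # all-positive input reduces to plain log2 + quantile normalization
  pos <- abs(d) + 1
  expect_equal(signed_normalize(pos), log2_quantile_normalize(pos))
  # negating one strain's differences flips signs, magnitudes unchanged
  d2 <- d; d2[, 4] <- -d2[, 4]
  out2 <- signed_normalize(d2)
  expect_equal(abs(out2), abs(out))
  expect_equal(out2[, 4], -out[, 4])
})

test_that("PC selection applies the variance-share rule and covariate screen", {
  set.seed(6)
  n <- 40; G <- 200
  # two dominant directions plus faint noise
  v1 <- rnorm(n); v2 <- rnorm(n)
  expr <- outer(rnorm(G, 0, 3), v1) + outer(rnorm(G, 0, 2), v2) +
    matrix(rnorm(G * n, 0, 0.05), G, n)
  sel <- select_technical_pcs(expr, covariates = NULL)
  expect_true(all(c(1, 2) %in% sel$indices))
  expect_true(all(sel$var_share[sel$indices] >
                    0.02 - 1e-12))
  # var_fraction = 1 and no covariates: nothing selected
  none <- select_technical_pcs(expr, var_fraction = 1)
  expect_length(none$indices, 0)

  # a tiny-variance PC that separates two pools is still selected
  pool <- rep(c("a", "b"), each = n / 2)
  expr2 <- expr + outer(rep(0.02, G), ifelse(pool == "a", 1, -1))
  sel2 <- select_technical_pcs(expr2, covariates = data.frame(pool = pool),
                               var_fraction = 0.02)
  pool_assoc <- apply(sel2$covariate_p, 1, min, na.rm = TRUE)
  assoc_pc <- which(pool_assoc < 1e-6)
  expect_true(length(assoc_pc) >= 1)
  expect_true(all(assoc_pc %in% sel2$indices))
  expect_error(select_technical_pcs(matrix(1, 5, 5)),
               class = "mppeqtl_degenerate_pca")
})

test_that("PC regression residuals match per-gene OLS and are orthogonal", {
  set.seed(8)
  expr <- matrix(rnorm(50 * 20), 50, 20)
  scores <- matrix(rnorm(20 * 3), 20, 3)
  res <- regress_out_pcs(expr, scores)
  expect_equal(unname(res), unname(oracle_residuals(expr, scores)),
               tolerance = 1e-10)
  expect_lt(max(abs(res %*% scores)), 1e-8)
  # empty selection: mean-centring only
  res0 <- regress_out_pcs(expr, matrix(numeric(0), 20, 0))
  expect_equal(unname(res0), unname(expr - rowMeans(expr)))
  # expression equal to a score vector vanishes
  res1 <- regress_out_pcs(rbind(scores[, 1]), scores)
  expect_lt(max(abs(res1)), 1e-10)
  expect_error(regress_out_pcs(expr, cbind(scores[, 1], scores[, 1])),
               class = "mppeqtl_rank_deficient")
})

test_that("inverse-normal transform yields fixed normal quantiles", {
  out <- inverse_normal_transform(rbind(g = c(5, 1, 9)))
  expect_equal(round(unname(out[1, ]), 4), c(0, -0.9674, 0.9674))
  # rank invariance under monotone transforms
  set.seed(10)
  x <- matrix(rnorm(5 * 20), 5, 20)
  expect_equal(inverse_normal_transform(x),
               inverse_normal_transform(exp(x)))
  expect_lt(max(abs(rowMeans(inverse_normal_transform(x)))), 1e-12)
  expect_error(inverse_normal_transform(x[, 1:2]),
               class = "mppeqtl_invalid_argument")
})

test_that("trait preparation composes the documented steps and removes batch structure", {
  study <- simulate_study(n_strains = 48, n_chromosomes = 1,
                          chrom_length_bp = 1e6, n_genes = 300,
                          n_cis = 0, n_trans = 0, batch_sd = 1.5,
                          nb_dispersion = 0.02, seed = 15)
  counts <- filter_low_expression(study$counts, 10, 47)
  tm <- prepare_trait_matrix(counts, study$samples, "gut-copper")
  expect_identical(attr(tm, "dataset"), "gut-copper")
  expect_identical(attr(tm, "provenance")[1], "log2_quantile_normalize")
  expect_match(attr(tm, "provenance")[2], "^regress_out_pcs")
  expect_identical(attr(tm, "provenance")[3], "inverse_normal_transform")
  expect_false(anyNA(tm))
  expect_equal(sort(colnames(tm)), sort(unique(study$samples$strain)))

  # a strong planted pool batch effect is removed: before preparation the
  # pool term dominates most genes, afterwards it is null-like
  use <- study$samples[study$samples$tissue == "gut" &
                         study$samples$treatment == "copper", ]
  raw <- log2(counts[, use$sample_id] + 1)
  pool_raw <- factor(use$pool)
  pool <- factor(use$pool[match(colnames(tm), use$strain)])
  p_raw <- apply(raw[1:150, ], 1, function(y)
    anova(lm(y ~ pool_raw))[["Pr(>F)"]][1])
  p_post <- apply(tm[1:150, ], 1, function(y)
    anova(lm(y ~ pool))[["Pr(>F)"]][1])
  expect_gt(mean(p_raw < 0.01), 0.9)
  expect_lt(mean(p_post < 0.01), 0.05)

  # response provenance starts with the paired difference
  tr <- prepare_trait_matrix(counts, study$samples, "gut-response")
  expect_identical(attr(tr, "provenance")[1:2],
                   c("compute_response", "signed_normalize"))
})
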