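test_that("marker map is an arithmetic grid with the expected cM conversion", {
  map <- simulate_marker_map(1, 1e5, 1e4, 2)
  expect_equal(nrow(map), 11)
  expect_equal(map$pos_bp, seq(0, 1e5, by = 1e4))
  expect_equal(map$pos_cM, seq(0, 0.2, by = 0.02))
  expect_equal(unique(diff(map$pos_bp)), 1e4)

  two <- simulate_marker_map(2, 1e5, 1e4, 2)
  expect_equal(nrow(two), 22)
  expect_false(anyDuplicated(two$marker_id) > 0)
  expect_error(simulate_marker_map(1, 1e5, 0, 2),
               class = "mppeqtl_invalid_argument")
})

test_that("RIL genomes are founder mosaics with valid probabilities", {
  map <- simulate_marker_map(2, 3e5, 1e4, 20)
  gen <- simulate_ril_genomes(map, 30, n_founders = 8,
                              expected_crossovers_per_chrom = 2,
                              prob_smoothing = 0, seed = 5)
  # one-hot probabilities at zero smoothing
  expect_true(all(gen$probs$P %in% c(0, 1)))
  sums <- apply(gen$probs$P, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # zero crossovers: each strain fixed for one founder per chromosome
  fixed <- simulate_ril_genomes(map, 20, expected_crossovers_per_chrom = 0,
                                seed = 2)
  for (ch in unique(map$chrom)) {
    sub <- fixed$assignments[, map$chrom == ch, drop = FALSE]
    expect_true(all(apply(sub, 1, function(x) length(unique(x))) == 1))
  }
  expect_error(simulate_ril_genomes(map, 5, n_founders = 1),
               class = "mppeqtl_invalid_argument")
  # determinism: identical seed gives bit-identical output
  again <- simulate_ril_genomes(map, 30, n_founders = 8,
                                expected_crossovers_per_chrom = 2,
                                prob_smoothing = 0, seed = 5)
  expect_identical(gen, again)
})

test_that("breakpoint counts are Poisson and ancestry is uniform over founders", {
  map <- simulate_marker_map(1, 3e5, 1e4, 20)
  gen <- simulate_ril_genomes(map, 10000, expected_crossovers_per_chrom = 2,
                              prob_smoothing = 0, seed = 11)
  n <- length(gen$n_breakpoints)
  se <- sqrt(2 / n)
  expect_lt(abs(mean(gen$n_breakpoints) - 2), 3 * se)

  # founder ancestry approximately uniform at each of a few markers
  for (m in c(1, 15, 31)) {
    tab <- tabulate(gen$assignments[, m], nbins = 8)
    expect_gt(chisq.test(tab)$p.value, 0.01)
  }
})

test_that("simulated counts have no strain structure without planted eQTL", {
  map <- simulate_marker_map(1, 2e5, 1e4, 20)
  gen <- simulate_ril_genomes(map, 40, seed = 3)
  samples <- make_sample_table(gen$probs$strains)
  truth <- plant_eqtl(simulate_gene_annotation(map, 5, seed = 1), map,
                      n_cis = 0, n_trans = 0, seed = 1)
  counts <- simulate_expression(truth, gen$probs, samples,
                                sprintf("g%04d", 1:5),
                                baseline_log2_mean = 7, baseline_sd = 0,
                                nb_dispersion = 1e-4, batch_sd = 0,
                                library_size_range = c(1, 1), seed = 9)
  # per-strain totals for one gene are Poisson-like around a common mean
  strain_tot <- tapply(counts[1, ], samples$strain[match(colnames(counts),
                                                         samples$sample_id)],
                       sum)
  expect_gt(chisq.test(as.numeric(strain_tot))$p.value, 0.01)
})

test_that("differential eQTL drive the copper-control difference, not control expression", {
  map <- simulate_marker_map(1, 3e5, 1e4, 20)
  gen <- simulate_ril_genomes(map, 60, prob_smoothing = 0.02, seed = 4)
  genes <- simulate_gene_annotation(map, 10, seed = 2)
  truth <- plant_eqtl(genes, map, n_cis = 1, n_trans = 0, effect_sd = 2,
                      acts_in_treatment = "differential", seed = 6)
  samples <- make_sample_table(gen$probs$strains, tissues = "head")
  counts <- simulate_expression(truth, gen$probs, samples, genes$gene_id,
                                nb_dispersion = 0.02, batch_sd = 0,
                                library_size_range = c(1, 1), seed = 8)
  g <- truth$target_gene
  dose <- drop(probs_at_marker(gen$probs, truth$eqtl_marker) %*%
                 as.numeric(truth[1, grep("^effect_", names(truth))]))
  cu <- samples$treatment == "copper"; ct <- samples$treatment == "control"
  strains_cu <- samples$strain[cu]
  lcu <- log2(counts[g, cu] + 1)
  lct <- log2(counts[g, ct][match(strains_cu, samples$strain[ct])] + 1)
  diff_cor <- cor.test(lcu - lct, dose[match(strains_cu, gen$probs$strains)])
  ctrl_cor <- cor.test(lct, dose[match(strains_cu, gen$probs$strains)])
  expect_lt(diff_cor$p.value, 1e-6)
  expect_gt(diff_cor$estimate, 0.5)
  expect_gt(ctrl_cor$p.value, 0.01)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  map <- simulate_marker_map(1, 5e4, 1e4, 20)
  gen <- simulate_ril_genomes(map, 100, seed = 5)
  samples <- make_sample_table(gen$probs$strains, tissues = "head",
                               treatments = "control")
  truth <- plant_eqtl(simulate_gene_annotation(map, 2, seed = 1), map, 0, 0,
                      seed = 1)
  counts <- simulate_expression(truth, gen$probs, samples,
                                c("g0001", "g0002"),
                                baseline_log2_mean = 8, baseline_sd = 0,
                                nb_dispersion = 1e-6, batch_sd = 0,
                                library_size_range = c(1, 1), seed = 2)
  ratio <- var(counts[1, ]) / mean(counts[1, ])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.4)
})

test_that("regressing noise-free log means on founder dosage recovers planted effects", {
  map <- simulate_marker_map(2, 3e5, 1e4, 20)
  gen <- simulate_ril_genomes(map, 96, prob_smoothing = 0.05, seed = 12)
  genes <- simulate_gene_annotation(map, 20, seed = 3)
  truth <- plant_eqtl(genes, map, n_cis = 2, n_trans = 2, effect_sd = 1.5,
                      seed = 13)
  samples <- make_sample_table(gen$probs$strains, tissues = "head",
                               treatments = "control")
  mu <- expected_log2_means(truth, gen$probs, samples, genes$gene_id)
  for (i in seq_len(nrow(truth))) {
    g <- truth$target_gene[i]
    X <- probs_at_marker(gen$probs, truth$eqtl_marker[i])
    beta <- coef(lm(mu[g, ] ~ X - 1))
    planted <- as.numeric(truth[i, grep("^effect_", names(truth))])
    # recovered up to an additive constant
    expect_lt(max(abs((beta - mean(beta)) - (planted - mean(planted)))),
              1e-8)
  }
})

test_that("unknown truth references are rejected", {
  map <- simulate_marker_map(1, 5e4, 1e4, 20)
  gen <- simulate_ril_genomes(map, 10, seed = 1)
  samples <- make_sample_table(gen$probs$strains)
  bad <- data.frame(target_gene = "gX", eqtl_marker = "nope",
                    acts_in_tissue = "both", acts_in_treatment = "both",
                    expected_class = "cis")
  bad[paste0("effect_", 1:8)] <- as.list(rep(0, 8))
  expect_error(simulate_expression(bad, gen$probs, samples, "gX"),
               class = "mppeqtl_invalid_reference")
  bad$target_gene <- "g0001"
  expect_error(simulate_expression(bad, gen$probs, samples, "gY"),
               class = "mppeqtl_invalid_reference")
})
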