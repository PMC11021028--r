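peak_row <- function(gene, chrom, pos, lo, hi) {
  data.frame(gene = gene, chrom = chrom, peak_cM = pos,
             ci_lo_cM = lo, ci_hi_cM = hi, stringsAsFactors = FALSE)
}

test_that("eQTL sharing applies the distance-or-overlap disjunction", {
  # distance 1.2 <= 1.5 cM, intervals disjoint: shared by the distance clause
  a <- peak_row("g1", "1", 5.0, 4.5, 5.5)
  b <- peak_row("g1", "1", 6.2, 6.0, 6.4)
  sh <- match_shared_eqtl(a, b)
  expect_equal(nrow(sh$matched), 1)
  expect_true(sh$matched$dist_ok)
  expect_false(sh$matched$overlap_ok)

  # far apart with disjoint intervals: both unique
  a <- peak_row("g1", "1", 10, 9, 11)
  b <- peak_row("g1", "1", 20, 19, 21)
  sh <- match_shared_eqtl(a, b)
  expect_equal(nrow(sh$matched), 0)
  expect_equal(sh$unique_a, 1L)
  expect_equal(sh$unique_b, 1L)

  # distant peaks with overlapping intervals: shared by the overlap clause
  a <- peak_row("g1", "1", 10, 8, 14)
  b <- peak_row("g1", "1", 13.5, 12, 15)
  sh <- match_shared_eqtl(a, b)
  expect_equal(nrow(sh$matched), 1)
  expect_false(sh$matched$dist_ok)
  expect_true(sh$matched$overlap_ok)

  # different chromosomes never share
  b2 <- peak_row("g1", "2", 5.0, 4.5, 5.5)
  expect_equal(nrow(match_shared_eqtl(peak_row("g1", "1", 5, 4.5, 5.5),
                                      b2)$matched), 0)
})

test_that("sharing is symmetric, per gene, and matches each peak once", {
  set.seed(50)
  mk <- function(n, genes) {
    pos <- runif(n, 0, 50)
    peak_row(sample(genes, n, TRUE), sample(c("1", "2"), n, TRUE),
             pos, pos - runif(n, 0.5, 3), pos + runif(n, 0.5, 3))
  }
  for (i in 1:5) {
    a <- mk(12, c("g1", "g2", "g3"))
    b <- mk(10, c("g1", "g2", "g4"))
    ab <- match_shared_eqtl(a, b)
    ba <- match_shared_eqtl(b, a)
    expect_equal(nrow(ab$matched), nrow(ba$matched))
    expect_equal(ab$matched[order(ab$matched$idx_a), c("idx_a", "idx_b")],
                 setNames(ba$matched[order(ba$matched$idx_b),
                                     c("idx_b", "idx_a")],
                          c("idx_a", "idx_b")),
                 ignore_attr = TRUE)
    expect_false(anyDuplicated(ab$matched$idx_a) > 0)
    expect_false(anyDuplicated(ab$matched$idx_b) > 0)
    # partition: every peak either matched or unique
    expect_setequal(c(ab$matched$idx_a, ab$unique_a), seq_len(nrow(a)))
    # cross-gene peaks are never matched
    expect_true(all(a$gene[ab$matched$idx_a] == b$gene[ab$matched$idx_b]))
  }
  # identical peak lists: everything matches, nothing unique
  a <- mk(8, c("g1", "g2"))
  self <- match_shared_eqtl(a, a)
  expect_equal(nrow(self$matched), 8)
  expect_length(self$unique_a, 0)
  expect_length(self$unique_b, 0)
})

test_that("founder-effect correlations behave as Pearson r", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(founder_effect_correlation(v, v), 1)
  expect_equal(founder_effect_correlation(v, -v), -1)
  expect_equal(founder_effect_correlation(v, 2 * v), 1)
  expect_error(founder_effect_correlation(v, rep(1, 8)),
               class = "mppeqtl_undefined_correlation")
  expect_error(founder_effect_correlation(v, v[1:4]),
               class = "mppeqtl_invalid_argument")
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  pop <- sprintf("g%02d", 1:20)
  study <- pop[1:5]
  sets <- list(allstudy = pop[1:5], whole = pop, none = pop[6:10])
  res <- hypergeom_enrichment(study, pop, sets)
  expect_equal(res$p_value[res$term == "allstudy"], 1 / choose(20, 5))
  expect_equal(res$p_value[res$term == "whole"], 1)      # k = n, K = N
  expect_equal(res$p_value[res$term == "none"], 1)       # k = 0
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_equal(res$adjusted_p, bh_adjust(res$p_value))

  # exhaustive-enumeration oracle on a small population
  popS <- sprintf("p%02d", 1:12)
  for (case in list(c(K = 4, n = 5, k = 2), c(K = 6, n = 4, k = 3),
                    c(K = 3, n = 6, k = 1))) {
    K <- case["K"]; n <- case["n"]; k <- case["k"]
    studyS <- c(popS[seq_len(k)], popS[seq(K + 1, K + n - k)])
    resS <- hypergeom_enrichment(studyS, popS,
                                 list(t = popS[seq_len(K)]))
    expect_equal(resS$p_value, oracle_hyper_p(12, K, n, k),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_enrichment("a", character(0), list()),
               class = "mppeqtl_invalid_argument")
  expect_error(hypergeom_enrichment("zz", pop, sets),
               class = "mppeqtl_invalid_argument")
})

test_that("planted shared eQTL are matched and effect correlations track sign", {
  set.seed(52)
  map <- simulate_marker_map(1, 59e4, 1e4, 50)  # 60 markers, 0.5 cM apart
  fp <- fixture_linked_probs(map, 96, seed = 53)
  genes <- data.frame(gene_id = sprintf("q%02d", 1:12), chrom = "1",
                      start_bp = 1e4 * (1:12), end_bp = 1e4 * (1:12) + 5e3)
  genes$pos_cM <- interpolate_cM(map, genes$chrom,
                                 (genes$start_bp + genes$end_bp) / 2)
  causal <- sample(10:50, 12)
  effs <- replicate(12, { e <- rnorm(8, 0, 1.5); e - mean(e) })
  make_traits <- function(sign, noise_seed) {
    set.seed(noise_seed)
    t(vapply(1:12, function(i) {
      dose <- drop(fp$P[, causal[i], ] %*% (sign * effs[, i]))
      dose + rnorm(96, 0, sd(dose) * 0.8)
    }, numeric(96))) -> tr
    dimnames(tr) <- list(genes$gene_id, fp$strains)
    tr
  }
  ta <- make_traits(1, 54); tb <- make_traits(-1, 55)
  thr <- setNames(rep(5, 12), genes$gene_id)
  pa <- peak_table(scan_all(ta, fp), thr, map, genes, ta, fp)
  pb <- peak_table(scan_all(tb, fp), thr, map, genes, tb, fp)
  sh <- match_shared_eqtl(pa, pb)
  both <- intersect(pa$gene, pb$gene)
  expect_gt(length(both), 8)
  # detected in both at the same planted locus: matched as shared
  expect_gte(nrow(sh$matched), length(both) - 1)
  # negated planted vectors: strongly negative effect correlations
  rs <- vapply(seq_len(nrow(sh$matched)), function(r) {
    ea <- as.numeric(pa[sh$matched$idx_a[r], paste0("effect_", 1:8)])
    eb <- as.numeric(pb[sh$matched$idx_b[r], paste0("effect_", 1:8)])
    founder_effect_correlation(ea, eb)
  }, numeric(1))
  expect_lt(median(rs), -0.8)

  # loci far apart are never matched: shift dataset B's peaks by 15 cM
  pb_far <- pb
  pb_far$peak_cM <- pb_far$peak_cM + 15
  pb_far$ci_lo_cM <- pb_far$ci_lo_cM + 15
  pb_far$ci_hi_cM <- pb_far$ci_hi_cM + 15
  expect_equal(nrow(match_shared_eqtl(pa, pb_far)$matched), 0)
})
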