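# Independent brute-force oracles used to cross-check the package's
# linear algebra. These deliberately use different code paths (lm(),
# explicit loops, exhaustive enumeration) from the implementations they
# verify.

# Haley-Knott LOD at one marker via two lm() fits
oracle_hk_lod <- function(trait, X) {
  n <- length(trait)
  full <- lm(trait ~ X - 1)
  null <- lm(trait ~ 1)
  rss1 <- sum(residuals(full)^2)
  rss0 <- sum(residuals(null)^2)
  (n / 2) * log10(rss0 / rss1)
}

# full LOD curve via per-marker lm()
oracle_hk_curve <- function(trait, probs) {
  vapply(seq_along(probs$markers), function(m) {
    oracle_hk_lod(trait, probs$P[, m, , drop = TRUE])
  }, numeric(1))
}

# naive TMM: explicit loops and sort-based trimming
oracle_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  uq <- sapply(seq_len(ncol(counts)),
               function(j) unname(quantile(counts[, j], 0.75)) / lib[j])
  ref <- which.min(abs(uq - mean(uq)))
  logf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    M <- c(); A <- c(); w <- c()
    for (g in seq_len(nrow(counts))) {
      o <- counts[g, j]; r <- counts[g, ref]
      if (o > 0 && r > 0) {
        M <- c(M, log2((o / lib[j]) / (r / lib[ref])))
        A <- c(A, 0.5 * log2((o / lib[j]) * (r / lib[ref])))
        w <- c(w, (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
      }
    }
    n <- length(M)
    if (n == 0 || max(abs(M)) < 1e-6) { logf[j] <- 0; next }
    keep <- rep(TRUE, n)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    logf[j] <- if (any(keep)) {
      sum(M[keep] / w[keep]) / sum(1 / w[keep])
    } else 0
  }
  f <- 2^logf
  f / exp(mean(log(f)))
}

# per-gene OLS residuals via lm()
oracle_residuals <- function(expr, scores) {
  t(apply(expr, 1, function(y) {
    if (ncol(scores) == 0) residuals(lm(y ~ 1)) else residuals(lm(y ~ scores))
  }))
}

# exact upper-tail hypergeometric p by exhaustive enumeration of study sets
oracle_hyper_p <- function(N, K, n, k) {
  pop <- seq_len(N)
  term <- seq_len(K)
  sets <- combn(N, n)
  hits <- apply(sets, 2, function(s) sum(s %in% term) >= k)
  mean(hits)
}

# linked founder probabilities from the mosaic generator (markers carry
# realistic spatial correlation, needed for peak-shape tests)
fixture_linked_probs <- function(map, n_strains, seed,
                                 crossovers = 3, smoothing = 0.05) {
  simulate_ril_genomes(map, n_strains,
                       expected_crossovers_per_chrom = crossovers,
                       prob_smoothing = smoothing, seed = seed)$probs
}

# small deterministic founder-probability fixture (smoothed one-hot,
# markers independent — fine for per-marker algebra, not for peak shapes)
fixture_probs <- function(n_strains, n_markers, n_founders = 8,
                          smoothing = 0.05, seed = 1) {
  set.seed(seed)
  P <- array(smoothing / (n_founders - 1),
             c(n_strains, n_markers, n_founders))
  ass <- matrix(sample.int(n_founders, n_strains * n_markers, TRUE),
                n_strains, n_markers)
  for (f in seq_len(n_founders)) P[, , f][ass == f] <- 1 - smoothing
  founder_probs(P, sprintf("s%03d", seq_len(n_strains)),
                sprintf("m%04d", seq_len(n_markers)))
}
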