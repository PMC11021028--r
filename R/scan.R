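# Batched Haley-Knott machinery.
#
# At each marker the full model regresses the trait on the F
# founder-probability columns with no separate intercept (the columns sum
# to one, which supplies the intercept); the null model is intercept-only.
# LOD = (n/2) * log10(RSS0 / RSS1).  For speed the orthonormal bases of
# all marker design matrices are precomputed once (QR per marker, rank
# aware) and stacked, so a scan of all genes at one permutation is a
# single matrix product.

# internal: stacked orthonormal bases Q (n x sum(rank_m)) and the marker
# index of each column
.scan_basis <- function(probs) {
  P <- probs$P
  n <- dim(P)[1]; M <- dim(P)[2]
  qs <- vector("list", M)
  for (m in seq_len(M)) {
    X <- P[, m, , drop = TRUE]
    qrX <- qr(X)
    r <- qrX$rank
    qs[[m]] <- qr.Q(qrX)[, seq_len(r), drop = FALSE]
  }
  ranks <- vapply(qs, ncol, integer(1))
  list(Q = do.call(cbind, qs), group = rep(seq_len(M), ranks), n = n, M = M)
}

# internal: LOD matrix (genes x markers) for trait matrix Y (strains x genes)
.scan_lod <- function(basis, Y, lod_cap = 50) {
  n <- basis$n
  Yc <- sweep(Y, 2, colMeans(Y))
  rss0 <- colSums(Yc^2)
  B <- crossprod(basis$Q, Yc)              # (sum ranks) x genes
  fit_ss <- rowsum(B^2, basis$group)       # markers x genes
  # the basis spans the intercept (prob columns sum to 1), so fitted SS
  # on centred traits is the model SS beyond the mean
  rss1 <- sweep(-fit_ss, 2, rss0, `+`)
  rss1[rss1 < 0] <- 0
  ratio <- sweep(rss1, 2, rss0, `/`)
  lod <- -(n / 2) * log10(pmax(ratio, 10^(-2 * lod_cap / n)))
  t(lod)                                    # genes x markers
}

#' Haley-Knott genome scan for one trait
#'
#' Regresses a trait on the founder additive probabilities at every marker
#' and returns the LOD curve: `(n/2) * log10(RSS0 / RSS1)` comparing the
#' F-founder model with the intercept-only null. Rank-deficient marker
#' designs (e.g. a founder absent at a marker) are handled by restricting
#' to the column space. Perfect fits are capped at `lod_cap`.
#'
#' @param trait Numeric vector, one value per strain, no missing values.
#' @param probs A `founder_probs` aligned with the trait (same strain
#'   order).
#' @param lod_cap Ceiling applied when RSS1 underflows (noise-free data).
#' @return Named numeric LOD vector over markers.
#' @export
hk_scan <- function(trait, probs, lod_cap = 50) {
  n <- length(trait)
  if (n != length(probs$strains)) {
    stop_mpp("trait length does not match strain count",
             "mppeqtl_invalid_argument")
  }
  if (anyNA(trait)) {
    stop_mpp("missing trait values are not allowed",
             "mppeqtl_invalid_argument")
  }
  if (n < dim(probs$P)[3] + 1) {
    stop_mpp("fewer strains than founders + 1: model underdetermined",
             "mppeqtl_underdetermined")
  }
  basis <- .scan_basis(probs)
  lod <- .scan_lod(basis, matrix(trait, ncol = 1), lod_cap = lod_cap)[1, ]
  names(lod) <- probs$markers
  lod
}

#' Genome scans for all genes of a trait matrix
#'
#' Runs [hk_scan()] for every gene using batched linear algebra (the
#' results are identical to the per-gene scans). Strains are aligned by
#' name between the trait matrix and the probabilities.
#'
#' @param traits Numeric matrix, genes x strains (a `trait_matrix`).
#' @param probs A `founder_probs`.
#' @param lod_cap Ceiling for perfect fits.
#' @return An `eqtl_scan` object: list with `lod` (genes x markers
#'   matrix), `genes`, `markers`, `n_strains`.
#' @export
scan_all <- function(traits, probs, lod_cap = 50) {
  missing_strains <- setdiff(colnames(traits), probs$strains)
  if (length(missing_strains) > 0) {
    stop_mpp(paste("strains absent from founder probabilities:",
                   paste(missing_strains, collapse = ", ")),
             "mppeqtl_alignment_error")
  }
  probs_sub <- subset_probs(probs, colnames(traits))
  basis <- .scan_basis(probs_sub)
  lod <- .scan_lod(basis, t(traits), lod_cap = lod_cap)
  dimnames(lod) <- list(rownames(traits), probs_sub$markers)
  structure(list(lod = lod, genes = rownames(traits),
                 markers = probs_sub$markers, n_strains = ncol(traits)),
            class = "eqtl_scan")
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat(sprintf("eqtl_scan: %d genes x %d markers (n = %d strains); max LOD %.2f\n",
              length(x$genes), length(x$markers), x$n_strains, max(x$lod)))
  invisible(x)
}

#' Subset founder probabilities to a strain set
#'
#' @param probs A `founder_probs`.
#' @param strains Strain ids, in the desired order.
#' @return A `founder_probs` restricted and reordered to `strains`.
#' @export
subset_probs <- function(probs, strains) {
  idx <- match(strains, probs$strains)
  if (anyNA(idx)) {
    stop_mpp(paste("unknown strains:",
                   paste(strains[is.na(idx)], collapse = ", ")),
             "mppeqtl_alignment_error")
  }
  founder_probs(probs$P[idx, , , drop = FALSE], strains, probs$markers)
}

#' Gene-specific permutation LOD thresholds
#'
#' For each gene, permutes trait values among strains `n_perm` times,
#' records the genome-wide maximum LOD of each permuted scan, and returns
#' the empirical `(1 - alpha)` quantile (order statistic
#' `ceiling((1 - alpha) * n_perm)`) as that gene's significance
#' threshold. By default one set of permutation index vectors is shared
#' across genes per round, which lets each round be computed as a single
#' batched scan; per-gene independent permutations are available with
#' `share_permutations = FALSE`.
#'
#' @param traits Numeric matrix, genes x strains.
#' @param probs A `founder_probs`.
#' @param n_perm Number of permutations (>= 100; 1000 in routine use).
#' @param alpha Genome-wide significance level (0.05 gives the 95%
#'   threshold).
#' @param seed Integer seed; thresholds are deterministic given the seed.
#' @param share_permutations Share index vectors across genes per round.
#' @param lod_cap Ceiling for perfect fits.
#' @return Named numeric vector of per-gene thresholds.
#' @export
permutation_thresholds <- function(traits, probs, n_perm = 1000,
                                   alpha = 0.05, seed = 1L,
                                   share_permutations = TRUE,
                                   lod_cap = 50) {
  if (n_perm < 100) {
    stop_mpp("n_perm must be >= 100", "mppeqtl_invalid_argument")
  }
  if (alpha <= 0 || alpha >= 1) {
    stop_mpp("alpha must be in (0, 1)", "mppeqtl_invalid_argument")
  }
  probs_sub <- subset_probs(probs, colnames(traits))
  basis <- .scan_basis(probs_sub)
  Y <- t(traits)
  n <- nrow(Y); G <- ncol(Y)
  set.seed(seed)
  maxlod <- matrix(NA_real_, G, n_perm)
  for (r in seq_len(n_perm)) {
    if (share_permutations) {
      Yp <- Y[sample.int(n), , drop = FALSE]
    } else {
      Yp <- apply(Y, 2, function(col) col[sample.int(n)])
    }
    lod <- .scan_lod(basis, Yp, lod_cap = lod_cap)
    maxlod[, r] <- apply(lod, 1, max)
  }
  k <- ceiling((1 - alpha) * n_perm)
  thr <- apply(maxlod, 1, function(x) sort(x)[k])
  names(thr) <- rownames(traits)
  thr
}
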