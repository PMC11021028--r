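#' Filter genes with low expression
#'
#' Removes genes with zero counts across all samples, and genes lacking at
#' least `min_count` counts in at least `min_samples` samples. The defaults
#' follow the rule of removing genes with fewer than 10 counts in 47
#' samples, 47 being the number of samples in each three-way design cell.
#'
#' @param counts Integer count matrix, genes x samples.
#' @param min_count Minimum count per sample to score a sample as
#'   expressing the gene.
#' @param min_samples Minimum number of expressing samples required to
#'   retain a gene.
#' @return The count matrix restricted to retained genes, order preserved.
#' @export
filter_low_expression <- function(counts, min_count = 10, min_samples = 47) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0) {
    stop_mpp("empty count matrix", "mppeqtl_invalid_argument")
  }
  if (min_samples > ncol(counts)) {
    stop_mpp("min_samples exceeds the number of samples",
             "mppeqtl_invalid_argument")
  }
  keep <- rowSums(counts) > 0 &
    rowSums(counts >= min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

# internal: upper-quartile of library-size-scaled counts, used to pick the
# TMM reference sample
.uq_scaled <- function(counts, lib_size) {
  vapply(seq_len(ncol(counts)),
         function(j) quantile(counts[, j], 0.75, names = FALSE) / lib_size[j],
         numeric(1))
}

# internal: TMM log2 factor of sample `obs` against reference `ref`
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  o <- obs[keep] / n_obs
  r <- ref[keep] / n_ref
  M <- log2(o / r)
  A <- 0.5 * log2(o * r)
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
    (n_ref - ref[keep]) / (n_ref * ref[keep])
  n <- length(M)
  if (n == 0) return(0)
  if (max(abs(M)) < 1e-6) return(0)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  rkM <- rank(M); rkA <- rank(A)
  use <- rkM >= loM & rkM <= hiM & rkA >= loA & rkA <= hiA
  if (!any(use)) return(0)
  f <- sum(M[use] / w[use]) / sum(1 / w[use])
  if (!is.finite(f)) 0 else f
}

#' TMM normalization factors
#'
#' Computes per-sample scaling factors by the weighted trimmed mean of
#' M-values: log expression ratios against a reference sample are trimmed
#' on both M (log ratio) and A (absolute log expression), then averaged
#' with inverse asymptotic-variance weights. The reference is the sample
#' whose library-size-scaled upper-quartile count is closest to the mean
#' upper quartile. Genes with a zero count in either the sample or the
#' reference are excluded. Factors are centred so they multiply to 1.
#'
#' @param counts Count matrix, genes x samples; every sample must have a
#'   positive total.
#' @param logratio_trim Two-sided trim fraction on M-values.
#' @param abs_trim Two-sided trim fraction on A-values.
#' @return Named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop_mpp("sample with zero total count", "mppeqtl_invalid_argument")
  }
  uq <- .uq_scaled(counts, lib)
  ref_j <- which.min(abs(uq - mean(uq)))
  logf <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref_j], lib[j], lib[ref_j],
              logratio_trim, abs_trim)
  }, numeric(1))
  f <- 2^logf
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2 counts per million with TMM effective library sizes
#'
#' Expression unit used for the factorial linear model:
#' `log2((count + offset) / (effective library size + 2 * offset) * 1e6)`
#' with effective size = library size x TMM factor.
#'
#' @param counts Count matrix, genes x samples.
#' @param norm_factors Per-sample normalization factors (e.g. from
#'   [tmm_factors()]).
#' @param offset Count offset guarding against zeros.
#' @return Numeric matrix of log2-CPM values.
#' @export
log2_cpm <- function(counts, norm_factors = tmm_factors(counts),
                     offset = 0.5) {
  eff <- colSums(counts) * norm_factors
  t(log2(t(counts + offset) / (eff + 2 * offset) * 1e6))
}

#' Fit the full-factorial gene-wise linear model
#'
#' Ordinary least squares of each gene's expression on
#' `~ tissue * treatment * resistance_class + pool`: all main effects,
#' two-way interactions and the three-way interaction, plus pooling-batch
#' covariates absorbing plate/library-pool/flowcell technical variation.
#'
#' @param log_expr Numeric matrix, genes x samples, typically log2-CPM.
#' @param samples A `sample_table` aligned with the columns of `log_expr`.
#' @param formula Model formula over sample-table columns.
#' @return An object of class `de_fit`: list with `coefficients`
#'   (genes x coefficients), `s2` (residual variances), `df` (residual
#'   degrees of freedom, shared by all genes), `design`, `xtx_inv` and
#'   `residuals`.
#' @export
fit_factorial_de <- function(log_expr, samples,
                             formula = ~ tissue * treatment *
                               resistance_class + pool) {
  stopifnot(ncol(log_expr) == nrow(samples))
  dat <- as.data.frame(samples)
  for (v in c("tissue", "treatment", "resistance_class", "pool")) {
    if (v %in% names(dat)) dat[[v]] <- factor(dat[[v]])
  }
  X <- model.matrix(formula, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_mpp(paste("design matrix is rank deficient; confounded columns:",
                   paste(dropped, collapse = ", ")),
             "mppeqtl_rank_deficient")
  }
  n <- nrow(X); p <- ncol(X)
  fit <- lm.fit(X, t(log_expr))
  # lm.fit drops to vectors for a single gene; rebuild dimnames explicitly
  coefs <- t(matrix(fit$coefficients, nrow = p,
                    dimnames = list(colnames(X), rownames(log_expr))))
  res <- t(matrix(fit$residuals, nrow = n,
                  dimnames = list(colnames(log_expr), rownames(log_expr))))
  df <- n - p
  s2 <- rowSums(res^2) / df
  structure(list(coefficients = coefs, s2 = s2, df = df, design = X,
                 xtx_inv = chol2inv(chol(crossprod(X))), residuals = res),
            class = "de_fit")
}

#' Moderated t-tests for contrasts of a factorial fit
#'
#' Applies empirical-Bayes variance moderation ([ebayes_moderate()]) and
#' computes moderated t-statistics, p-values and BH-adjusted p-values for
#' a set of contrasts expressed as vectors over the fitted coefficients.
#' By default every non-intercept, non-pool coefficient is tested — the
#' three headline contrasts (gut vs head tissue, copper vs control
#' treatment, sensitive vs resistant class) and all their interactions.
#'
#' @param fit A `de_fit` object.
#' @param contrasts Numeric matrix, coefficients x contrasts; default the
#'   identity on the factorial (non-pool) coefficients.
#' @param fdr FDR threshold defining the `significant` flag.
#' @return A `de_result` data frame in long format: `gene`, `contrast`,
#'   `logFC`, `t`, `p_value`, `adjusted_p`, `significant`. BH adjustment
#'   is applied within each contrast.
#' @export
de_test <- function(fit, contrasts = NULL, fdr = 0.05) {
  cn <- colnames(fit$coefficients)
  if (is.null(contrasts)) {
    keep <- setdiff(cn, c("(Intercept)", grep("^pool", cn, value = TRUE)))
    contrasts <- diag(length(cn))[, match(keep, cn), drop = FALSE]
    dimnames(contrasts) <- list(cn, keep)
  }
  mod <- ebayes_moderate(fit$s2, fit$df)
  out <- vector("list", ncol(contrasts))
  for (k in seq_len(ncol(contrasts))) {
    cvec <- contrasts[, k]
    lfc <- drop(fit$coefficients %*% cvec)
    unscaled <- sqrt(drop(t(cvec) %*% fit$xtx_inv %*% cvec))
    tstat <- lfc / (sqrt(mod$s2_post) * unscaled)
    p <- 2 * pt(-abs(tstat), df = mod$df_total)
    adj <- bh_adjust(p)
    out[[k]] <- data.frame(gene = rownames(fit$coefficients),
                           contrast = colnames(contrasts)[k],
                           logFC = lfc, t = tstat, p_value = p,
                           adjusted_p = adj, significant = adj < fdr,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("de_result", "data.frame")
  res
}

# internal: Newton inversion of the trigamma function (solve
# trigamma(y) = x), used by the moment-matching hyperparameter estimator
trigamma_inverse <- function(x, tol = 1e-10, maxit = 100) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in seq_len(maxit)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < tol) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Shrinks per-gene residual variances toward a common prior by fitting a
#' scaled F-distribution to the observed variances: hyperparameters
#' (`d0` prior degrees of freedom, `s0_sq` prior variance) are estimated by
#' moment matching on log variances using digamma/trigamma inversion, and
#' each moderated variance is `(d0 * s0_sq + df * s2) / (d0 + df)`.
#' Degenerate (near-equal) variances give an effectively infinite prior
#' df, capped at `1e6`.
#'
#' @param s2 Per-gene residual variances (length >= 3).
#' @param df Residual degrees of freedom (scalar or per gene).
#' @return List with `d0`, `s0_sq`, `s2_post` (moderated variances) and
#'   `df_total = df + d0` (capped) for moderated t-tests.
#' @export
ebayes_moderate <- function(s2, df) {
  if (length(s2) < 3) {
    stop_mpp("need at least 3 genes to estimate hyperparameters",
             "mppeqtl_hyperparameter_error")
  }
  if (any(s2 < 0) || any(df < 1)) {
    stop_mpp("variances must be >= 0 and df >= 1",
             "mppeqtl_invalid_argument")
  }
  df <- rep_len(df, length(s2))
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.na(evar) || evar <= 0) {
    # degenerate (near-identical) variances: infinite prior df; the prior
    # variance is then just the average observed variance
    d0 <- 1e6
    s0_sq <- mean(s2)
  } else {
    d0 <- min(2 * trigamma_inverse(evar), 1e6)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post, df_total = df + d0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted p-values are multiplied by `m / rank`,
#' a running minimum is taken from the largest rank down, values are
#' capped at 1, and the input order is restored.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_mpp("p-values must lie in [0, 1]", "mppeqtl_invalid_argument")
  }
  m <- length(p_values)
  ord <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(p_values[ord] * m / seq(m, 1)))
  adj[order(ord)]
}
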