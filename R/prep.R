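#' Log2 transform and quantile normalize counts
#'
#' First preparation step for eQTL traits: `log2(count + offset)` followed
#' by column-wise quantile normalization to the mean empirical
#' distribution, so that afterwards every column has identical sorted
#' values.
#'
#' @param counts Non-negative matrix, genes x samples (>= 2 samples).
#' @param offset Additive offset before the log (zeros are common).
#' @return Numeric matrix of normalized log2 values.
#' @export
log2_quantile_normalize <- function(counts, offset = 1) {
  if (is.null(dim(counts)) || ncol(counts) < 2) {
    stop_mpp("quantile normalization needs at least 2 samples",
             "mppeqtl_invalid_argument")
  }
  if (any(counts < 0)) {
    stop_mpp("counts must be non-negative", "mppeqtl_invalid_argument")
  }
  quantile_normalize(log2(counts + offset))
}

#' Quantile normalize the columns of a matrix
#'
#' Each column is mapped onto the across-column mean of the order
#' statistics; ties within a column receive the mean of the reference
#' quantiles they span.
#'
#' @param x Numeric matrix.
#' @return Matrix with identical sorted values in every column.
#' @export
quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # average ranks may be half-integers; interpolate the reference
    approx(seq_along(ref), ref, xout = rk)$y
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Copper-response expression: copper minus control
#'
#' Element-wise difference of paired counts: expression under copper
#' conditions minus expression under control conditions for each strain.
#' Positive values indicate copper-induced genes, negative values
#' copper-repressed genes.
#'
#' @param copper_counts,control_counts Matrices with identical gene rows
#'   and columns named by strain; strains must pair one-to-one.
#' @return Signed numeric matrix genes x strains (copper - control).
#' @export
compute_response <- function(copper_counts, control_counts) {
  if (!identical(rownames(copper_counts), rownames(control_counts))) {
    stop_mpp("gene lists differ between treatments",
             "mppeqtl_invalid_argument")
  }
  a <- colnames(copper_counts); b <- colnames(control_counts)
  unpaired <- c(setdiff(a, b), setdiff(b, a))
  if (length(unpaired) > 0) {
    stop_mpp(paste("strains without a treatment pair:",
                   paste(sort(unique(unpaired)), collapse = ", ")),
             "mppeqtl_missing_pair")
  }
  copper_counts - control_counts[, a, drop = FALSE]
}

#' Sign-preserving normalization of response values
#'
#' Log2 transformation and quantile normalization applied to the absolute
#' values of the copper-response differences, with the original sign
#' reassigned afterwards. Zero differences map to exactly zero.
#'
#' @param response Signed matrix from [compute_response()].
#' @param offset Additive offset before the log of the absolute values.
#' @return Signed normalized matrix with the input's sign pattern.
#' @export
signed_normalize <- function(response, offset = 1) {
  v <- log2_quantile_normalize(abs(response), offset = offset)
  v * sign(response)
}

#' Select technical principal components
#'
#' PCA over strains (columns) of an expression matrix; a component is
#' selected for removal if it explains more than `var_fraction` of the
#' total variance, or if it is associated with a known technical covariate
#' (one-way ANOVA for categorical covariates, Pearson correlation test for
#' numeric ones, at level `alpha` per PC x covariate).
#'
#' @param expr Numeric matrix, genes x strains.
#' @param covariates Data frame of per-strain technical covariates
#'   (e.g. pool), or `NULL`.
#' @param var_fraction Variance-share threshold (default 2%).
#' @param alpha Significance level of the covariate association screen.
#' @return List with `indices` (ordered selected PC indices), `scores`
#'   (strains x selected PCs), `var_share` (all PCs) and
#'   `covariate_p` (matrix of association p-values, PCs x covariates).
#' @export
select_technical_pcs <- function(expr, covariates = NULL,
                                 var_fraction = 0.02, alpha = 0.05) {
  if (nrow(expr) < 2 || all(apply(expr, 1, sd) == 0)) {
    stop_mpp("expression matrix is constant; PCA is degenerate",
             "mppeqtl_degenerate_pca")
  }
  pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- sum(pc$sdev > 1e-12)
  sel <- which(share[seq_len(n_pc)] > var_fraction)
  cov_p <- NULL
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    cov_p <- matrix(NA_real_, n_pc, ncol(covariates),
                    dimnames = list(paste0("PC", seq_len(n_pc)),
                                    names(covariates)))
    for (k in seq_len(n_pc)) {
      for (v in seq_len(ncol(covariates))) {
        cv <- covariates[[v]]
        if (is.numeric(cv)) {
          if (sd(cv) == 0) next
          cov_p[k, v] <- cor.test(pc$x[, k], cv)$p.value
        } else {
          cv <- factor(cv)
          if (nlevels(cv) < 2) next
          fit <- aov(pc$x[, k] ~ cv)
          cov_p[k, v] <- summary(fit)[[1]][["Pr(>F)"]][1]
        }
      }
    }
    assoc <- which(apply(cov_p, 1, function(p) any(p < alpha, na.rm = TRUE)))
    sel <- sort(union(sel, assoc))
  }
  list(indices = sel,
       scores = pc$x[, sel, drop = FALSE],
       var_share = share,
       covariate_p = cov_p)
}

#' Regress principal components out of expression
#'
#' Per gene, returns the OLS residuals of expression on an intercept plus
#' the selected PC score vectors; with an empty selection this is simple
#' per-gene mean-centring.
#'
#' @param expr Numeric matrix, genes x strains.
#' @param scores Strains x PCs score matrix (possibly zero columns).
#' @return Residual matrix, same shape as `expr`, orthogonal to every
#'   score vector.
#' @export
regress_out_pcs <- function(expr, scores) {
  n <- ncol(expr)
  if (is.null(scores)) scores <- matrix(numeric(0), n, 0)
  if (nrow(scores) != n) {
    stop_mpp("score length does not match strain count",
             "mppeqtl_invalid_argument")
  }
  X <- cbind(`(Intercept)` = 1, scores)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_mpp("collinear PC scores", "mppeqtl_rank_deficient")
  }
  res <- t(qr.resid(qrX, t(expr)))
  dimnames(res) <- dimnames(expr)
  res
}

#' Rank-based inverse-normal transformation
#'
#' Per gene, values are replaced by standard normal quantiles of their
#' ranks, `qnorm((rank - 0.5) / n)`, with average ranks for ties. The
#' output of each gene is a permutation of fixed normal quantiles, the
#' final normalization applied to residuals before eQTL scanning.
#'
#' @param residuals Numeric matrix, genes x strains (>= 3 strains).
#' @return Matrix of inverse-normal scores.
#' @export
inverse_normal_transform <- function(residuals) {
  if (ncol(residuals) < 3) {
    stop_mpp("inverse-normal transform needs >= 3 strains",
             "mppeqtl_invalid_argument")
  }
  n <- ncol(residuals)
  out <- t(apply(residuals, 1, function(x) {
    qnorm((rank(x, ties.method = "average") - 0.5) / n)
  }))
  dimnames(out) <- dimnames(residuals)
  out
}

#' Prepare an analysis-ready trait matrix for one dataset
#'
#' Composes the full preparation pipeline for one of the six
#' tissue x treatment datasets (Head/Gut x Control/Copper/Response).
#' For Control and Copper datasets:
#' filter (done upstream) -> log2 + quantile normalization -> PC selection
#' and removal -> inverse-normal transform. For Response datasets the
#' first step is replaced by the signed copper-minus-control construction
#' followed by sign-preserving normalization. A provenance record of the
#' applied steps and selected PCs is attached.
#'
#' @param counts Filtered count matrix, genes x samples, for the dataset's
#'   tissue; for Control/Copper the treatment's samples, columns named by
#'   sample; for Response both treatments are required.
#' @param samples A `sample_table` covering the columns of `counts`.
#' @param dataset Label: tissue and trait, e.g. `"head-control"`,
#'   `"gut-response"`.
#' @param var_fraction,alpha PC-selection parameters.
#' @param offset Log offset.
#' @return A `trait_matrix`: genes x strains matrix with attributes
#'   `dataset`, `provenance` (character vector of steps), `pcs_removed`
#'   and `var_share`.
#' @export
prepare_trait_matrix <- function(counts, samples, dataset,
                                 var_fraction = 0.02, alpha = 0.05,
                                 offset = 1) {
  parts <- strsplit(tolower(dataset), "-")[[1]]
  if (length(parts) != 2 ||
      !parts[2] %in% c("control", "copper", "response")) {
    stop_mpp("dataset must be '<tissue>-<control|copper|response>'",
             "mppeqtl_invalid_argument")
  }
  tissue <- parts[1]; trait <- parts[2]
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (any(is.na(samples$sample_id))) {
    stop_mpp("count columns missing from sample table",
             "mppeqtl_invalid_argument")
  }
  keep <- samples$tissue == tissue
  counts <- counts[, keep, drop = FALSE]
  samples <- samples[keep, , drop = FALSE]
  prov <- character(0)

  if (trait %in% c("control", "copper")) {
    use <- samples$treatment == trait
    sub <- counts[, use, drop = FALSE]
    colnames(sub) <- samples$strain[use]
    strain_cov <- samples[use, c("pool", "resistance_class"), drop = FALSE]
    norm <- log2_quantile_normalize(sub, offset = offset)
    prov <- c(prov, "log2_quantile_normalize")
  } else {
    cu <- samples$treatment == "copper"
    ct <- samples$treatment == "control"
    paired <- intersect(samples$strain[cu], samples$strain[ct])
    dropped <- setdiff(union(samples$strain[cu], samples$strain[ct]), paired)
    if (length(dropped) > 0) {
      warning(sprintf("dropping %d strain(s) without both treatments: %s",
                      length(dropped), paste(dropped, collapse = ", ")))
    }
    cu_m <- counts[, cu, drop = FALSE]; colnames(cu_m) <- samples$strain[cu]
    ct_m <- counts[, ct, drop = FALSE]; colnames(ct_m) <- samples$strain[ct]
    cu_m <- cu_m[, paired, drop = FALSE]
    ct_m <- ct_m[, paired, drop = FALSE]
    resp <- compute_response(cu_m, ct_m)
    prov <- c(prov, "compute_response")
    norm <- signed_normalize(resp, offset = offset)
    prov <- c(prov, "signed_normalize")
    strain_cov <- samples[cu, c("pool", "resistance_class"), drop = FALSE]
    strain_cov <- strain_cov[match(paired, samples$strain[cu]), , drop = FALSE]
  }

  pcs <- select_technical_pcs(norm, covariates = strain_cov,
                              var_fraction = var_fraction, alpha = alpha)
  resid <- regress_out_pcs(norm, pcs$scores)
  prov <- c(prov, sprintf("regress_out_pcs[%s]",
                          paste(pcs$indices, collapse = ",")))
  traits <- inverse_normal_transform(resid)
  prov <- c(prov, "inverse_normal_transform")
  structure(traits, dataset = dataset, provenance = prov,
            pcs_removed = pcs$indices, var_share = pcs$var_share,
            class = c("trait_matrix", "matrix", "array"))
}
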