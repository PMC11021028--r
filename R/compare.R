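#' Match shared eQTL between two datasets
#'
#' Per gene, peaks from dataset A are matched to peaks of the same gene in
#' dataset B. Two peaks are candidate matches if they lie on the same
#' chromosome and either their peak positions are within `window_cM` of
#' each other or their support intervals overlap (the disjunction is
#' applied literally; both clause outcomes are recorded). Among candidate
#' pairs, matching is greedy by smallest peak-position distance, each peak
#' matched at most once. Matching is symmetric in A and B.
#'
#' @param peaks_a,peaks_b Peak tables (from [peak_table()]) on a shared
#'   map.
#' @param window_cM Peak-distance window.
#' @return A `sharing_report` list: `matched` (data frame of pairs with
#'   per-clause outcomes `dist_ok`, `overlap_ok` and the row indices
#'   `idx_a`, `idx_b`), `unique_a`, `unique_b` (row indices of unmatched
#'   peaks) and `criterion` (record of the rule applied).
#' @export
match_shared_eqtl <- function(peaks_a, peaks_b, window_cM = 1.5) {
  pairs <- list()
  genes <- intersect(unique(peaks_a$gene), unique(peaks_b$gene))
  for (g in genes) {
    ia <- which(peaks_a$gene == g)
    ib <- which(peaks_b$gene == g)
    cand <- expand.grid(a = ia, b = ib, KEEP.OUT.ATTRS = FALSE)
    if (nrow(cand) == 0) next
    same_chr <- peaks_a$chrom[cand$a] == peaks_b$chrom[cand$b]
    dist <- abs(peaks_a$peak_cM[cand$a] - peaks_b$peak_cM[cand$b])
    dist_ok <- same_chr & dist <= window_cM
    overlap_ok <- same_chr &
      peaks_a$ci_lo_cM[cand$a] <= peaks_b$ci_hi_cM[cand$b] &
      peaks_b$ci_lo_cM[cand$b] <= peaks_a$ci_hi_cM[cand$a]
    ok <- dist_ok | overlap_ok
    cand <- cbind(cand, dist = dist, dist_ok = dist_ok,
                  overlap_ok = overlap_ok)[ok, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$a, cand$b), , drop = FALSE]
    used_a <- integer(0); used_b <- integer(0)
    for (r in seq_len(nrow(cand))) {
      if (cand$a[r] %in% used_a || cand$b[r] %in% used_b) next
      used_a <- c(used_a, cand$a[r]); used_b <- c(used_b, cand$b[r])
      pairs[[length(pairs) + 1]] <- data.frame(
        gene = g, idx_a = cand$a[r], idx_b = cand$b[r],
        dist_cM = cand$dist[r], dist_ok = cand$dist_ok[r],
        overlap_ok = cand$overlap_ok[r], stringsAsFactors = FALSE)
    }
  }
  matched <- if (length(pairs) > 0) {
    do.call(rbind, pairs)
  } else {
    data.frame(gene = character(0), idx_a = integer(0), idx_b = integer(0),
               dist_cM = numeric(0), dist_ok = logical(0),
               overlap_ok = logical(0), stringsAsFactors = FALSE)
  }
  rownames(matched) <- NULL
  structure(list(
    matched = matched,
    unique_a = setdiff(seq_len(nrow(peaks_a)), matched$idx_a),
    unique_b = setdiff(seq_len(nrow(peaks_b)), matched$idx_b),
    criterion = sprintf(
      "same chromosome and (|peak distance| <= %g cM or interval overlap)",
      window_cM)),
    class = "sharing_report")
}

#' @export
print.sharing_report <- function(x, ...) {
  cat(sprintf("sharing_report: %d matched, %d unique to A, %d unique to B\n",
              nrow(x$matched), length(x$unique_a), length(x$unique_b)))
  cat(" criterion:", x$criterion, "\n")
  invisible(x)
}

#' Correlation of founder effects between two eQTL
#'
#' Pearson correlation of two founder-effect vectors at matched eQTL,
#' used to ask whether a shared locus drives expression in the same
#' founder-allele direction in both datasets (e.g. Response vs Control
#' effects, where negative correlations indicate sign-flipping
#' genotype-by-treatment architecture).
#'
#' @param effects_a,effects_b Numeric F-vectors (length >= 3).
#' @return Pearson r.
#' @export
founder_effect_correlation <- function(effects_a, effects_b) {
  if (length(effects_a) != length(effects_b) || length(effects_a) < 3) {
    stop_mpp("effect vectors must have equal length >= 3",
             "mppeqtl_invalid_argument")
  }
  if (sd(effects_a) == 0 || sd(effects_b) == 0) {
    stop_mpp("zero variance in a founder-effect vector: correlation undefined",
             "mppeqtl_undefined_correlation")
  }
  cor(effects_a, effects_b)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per term: with population size `N`,
#' term size `K`, study size `n` and overlap `k`, the p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Gene sets are
#' intersected with the population before testing; BH adjustment is
#' applied across terms.
#'
#' @param study Character vector of study gene ids (subset of
#'   `population`).
#' @param population Character vector of background gene ids.
#' @param gene_sets Named list mapping term -> character vector of gene
#'   ids.
#' @param fdr FDR threshold for the `significant` flag.
#' @return An `enrichment_result` data frame: `term`, `N`, `K`, `n`, `k`,
#'   `p_value`, `adjusted_p`, `significant`.
#' @export
hypergeom_enrichment <- function(study, population, gene_sets, fdr = 0.05) {
  population <- unique(population)
  if (length(population) == 0) {
    stop_mpp("empty population", "mppeqtl_invalid_argument")
  }
  study <- unique(study)
  if (!all(study %in% population)) {
    stop_mpp("study genes must be a subset of the population",
             "mppeqtl_invalid_argument")
  }
  N <- length(population); n <- length(study)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(gene_sets[[term]]), population)
    K <- length(set)
    k <- length(intersect(set, study))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, N = N, K = K, n = n, k = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- bh_adjust(res$p_value)
  res$significant <- res$adjusted_p < fdr
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
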