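#' Call eQTL peaks from a LOD curve
#'
#' Per chromosome, candidate peaks are local maxima above the threshold.
#' The strongest is always kept; further local maxima are accepted only if
#' above threshold, separated from every already accepted peak by a valley
#' at least `lod_drop` below the lower of the two peaks, and at a distinct
#' marker. Ties in LOD break to the leftmost marker. Each peak's support
#' interval extends outward to the first markers whose LOD falls below
#' `peak LOD - lod_drop` (those flanking markers are included), clipped at
#' the chromosome ends. A 3-LOD drop is the default since a 2-LOD drop can
#' give overly narrow intervals at modest strain numbers.
#'
#' @param lod Named numeric LOD vector aligned with `map` markers.
#' @param threshold Significance threshold (from permutations).
#' @param map A `marker_map` whose markers match `lod`.
#' @param lod_drop Drop defining the support interval.
#' @return A data frame of raw peaks (no classification): `chrom`,
#'   `peak_marker`, `peak_bp`, `peak_cM`, `lod`, `ci_lo_marker`,
#'   `ci_lo_cM`, `ci_hi_marker`, `ci_hi_cM`, `n_above` (length of the
#'   contiguous above-threshold run containing the peak).
#' @export
call_peaks <- function(lod, threshold, map, lod_drop = 3.0) {
  stopifnot(length(lod) == nrow(map))
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    l <- lod[idx]
    m <- length(l)
    # local maxima: >= both neighbours, strictly greater than the
    # previous value (leftmost marker of any plateau)
    left <- c(Inf, l[-m]); right <- c(l[-1], -Inf)
    is_max <- l > left & l >= right
    is_max[1] <- l[1] >= right[1]
    cand <- which(is_max & l > threshold)
    if (length(cand) == 0) next
    cand <- cand[order(-l[cand], cand)]
    accepted <- integer(0)
    for (p in cand) {
      ok <- TRUE
      for (a in accepted) {
        lo <- min(p, a); hi <- max(p, a)
        valley <- min(l[lo:hi])
        if (l[p] == l[a] && p == a) { ok <- FALSE; break }
        if (valley > min(l[p], l[a]) - lod_drop) { ok <- FALSE; break }
      }
      if (ok) accepted <- c(accepted, p)
    }
    accepted <- sort(accepted)
    for (p in accepted) {
      drop_to <- l[p] - lod_drop
      lo <- p
      while (lo > 1 && l[lo] >= drop_to) lo <- lo - 1
      if (l[lo] >= drop_to) lo <- 1          # clipped at chromosome end
      hi <- p
      while (hi < m && l[hi] >= drop_to) hi <- hi + 1
      if (l[hi] >= drop_to) hi <- m
      # above-threshold run containing the peak
      run_lo <- p
      while (run_lo > 1 && l[run_lo - 1] > threshold) run_lo <- run_lo - 1
      run_hi <- p
      while (run_hi < m && l[run_hi + 1] > threshold) run_hi <- run_hi + 1
      gi <- idx[p]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        peak_marker = map$marker_id[gi],
        peak_bp = map$pos_bp[gi],
        peak_cM = map$pos_cM[gi],
        lod = l[p],
        ci_lo_marker = map$marker_id[idx[lo]],
        ci_lo_cM = map$pos_cM[idx[lo]],
        ci_hi_marker = map$marker_id[idx[hi]],
        ci_hi_cM = map$pos_cM[idx[hi]],
        n_above = run_hi - run_lo + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), peak_marker = character(0),
                      peak_bp = numeric(0), peak_cM = numeric(0),
                      lod = numeric(0), ci_lo_marker = character(0),
                      ci_lo_cM = numeric(0), ci_hi_marker = character(0),
                      ci_hi_cM = numeric(0), n_above = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter raw peaks
#'
#' Removes peaks whose above-threshold run consists of a single marker,
#' and peaks whose position falls outside their own support interval —
#' phenomena typical of limited sample size near telomeres and
#' centromeres. Surviving peaks are returned unchanged.
#'
#' @param peaks Raw peak data frame from [call_peaks()].
#' @return The filtered peak data frame.
#' @export
filter_peaks <- function(peaks) {
  if (nrow(peaks) == 0) return(peaks)
  keep <- peaks$n_above >= 2 &
    peaks$peak_cM >= peaks$ci_lo_cM & peaks$peak_cM <= peaks$ci_hi_cM
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a peak as cis or trans
#'
#' A peak is cis if it lies on the gene's chromosome and the gene's cM
#' position is inside the support interval or within `cis_window_cM` of
#' either boundary; otherwise (including any peak on a different
#' chromosome) it is trans. Wider support intervals therefore classify
#' more peaks as cis.
#'
#' @param peak One row of a peak data frame.
#' @param gene One row of a `gene_annotation` (fields `chrom`, `pos_cM`).
#' @param cis_window_cM Distance window around the interval boundaries.
#' @return `"cis"` or `"trans"`.
#' @export
classify_peak <- function(peak, gene, cis_window_cM = 1.5) {
  if (is.na(gene$chrom) || length(gene$chrom) == 0) {
    stop_mpp("gene chromosome unknown", "mppeqtl_invalid_reference")
  }
  if (peak$chrom != gene$chrom) return("trans")
  g <- gene$pos_cM
  if (g >= peak$ci_lo_cM && g <= peak$ci_hi_cM) return("cis")
  dist <- min(abs(g - peak$ci_lo_cM), abs(g - peak$ci_hi_cM))
  if (dist <= cis_window_cM) "cis" else "trans"
}

#' Founder effects and percent variance at a marker
#'
#' OLS regression of the trait on the F founder-probability columns at a
#' peak marker. Effects are reported centred to mean zero (trait units);
#' percent variance is `100 * (1 - RSS1 / RSS0)`, the share of trait
#' variance explained by founder ancestry at the marker. Rank-deficient
#' designs fall back to the minimum-norm (pseudo-inverse) solution with a
#' message.
#'
#' @param trait Numeric vector over strains.
#' @param probs_at_peak Strain x founder probability matrix (see
#'   [probs_at_marker()]).
#' @return List with `effects` (centred F-vector) and `percent_variance`.
#' @export
founder_effects <- function(trait, probs_at_peak) {
  stopifnot(length(trait) == nrow(probs_at_peak))
  X <- probs_at_peak
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    message("rank-deficient founder design at peak; using pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], trait)) / sv$d[pos])
    fitted <- X %*% beta
  } else {
    beta <- qr.coef(qrX, trait)
    fitted <- qr.fitted(qrX, trait)
  }
  rss1 <- sum((trait - fitted)^2)
  rss0 <- sum((trait - mean(trait))^2)
  pv <- if (rss0 > 0) 100 * (1 - rss1 / rss0) else NA_real_
  effects <- as.numeric(beta)
  effects <- effects - mean(effects)
  names(effects) <- colnames(probs_at_peak)
  list(effects = effects, percent_variance = pv)
}

#' Call, filter, classify and annotate peaks for a whole scan
#'
#' End-to-end peak table for an `eqtl_scan`: peaks are called per gene
#' with [call_peaks()], filtered with [filter_peaks()], classified
#' cis/trans against the gene annotation, and annotated with founder
#' effects and percent variance at the peak marker.
#'
#' @param scan An `eqtl_scan` from [scan_all()].
#' @param thresholds Named per-gene thresholds from
#'   [permutation_thresholds()].
#' @param map A `marker_map` matching the scan markers.
#' @param genes A `gene_annotation` (rows for all scanned genes).
#' @param traits The trait matrix that was scanned (genes x strains).
#' @param probs The `founder_probs` used for the scan.
#' @param lod_drop Support-interval drop.
#' @param cis_window_cM Cis classification window.
#' @return A peak table: one row per retained peak with gene, position,
#'   LOD, threshold, interval, class, percent variance and founder
#'   effects `effect_1` ... `effect_F`.
#' @export
peak_table <- function(scan, thresholds, map, genes, traits, probs,
                       lod_drop = 3.0, cis_window_cM = 1.5) {
  stopifnot(identical(scan$markers, map$marker_id))
  probs_sub <- subset_probs(probs, colnames(traits))
  nF <- dim(probs_sub$P)[3]
  out <- list()
  for (g in scan$genes) {
    thr <- thresholds[[g]]
    pk <- filter_peaks(call_peaks(scan$lod[g, ], thr, map,
                                  lod_drop = lod_drop))
    if (nrow(pk) == 0) next
    gene <- genes[genes$gene_id == g, ]
    for (i in seq_len(nrow(pk))) {
      cls <- if (nrow(gene) == 1) {
        classify_peak(pk[i, ], gene, cis_window_cM = cis_window_cM)
      } else NA_character_
      fe <- founder_effects(traits[g, ],
                            probs_at_marker(probs_sub, pk$peak_marker[i]))
      row <- data.frame(gene = g, pk[i, ], threshold = thr, class = cls,
                        percent_variance = fe$percent_variance,
                        stringsAsFactors = FALSE)
      row[paste0("effect_", seq_len(nF))] <- as.list(unname(fe$effects))
      out[[length(out) + 1]] <- row
    }
  }
  if (length(out) == 0) {
    base <- data.frame(gene = character(0), chrom = character(0),
                       peak_marker = character(0), peak_bp = numeric(0),
                       peak_cM = numeric(0), lod = numeric(0),
                       ci_lo_marker = character(0), ci_lo_cM = numeric(0),
                       ci_hi_marker = character(0), ci_hi_cM = numeric(0),
                       n_above = integer(0), threshold = numeric(0),
                       class = character(0), percent_variance = numeric(0),
                       stringsAsFactors = FALSE)
    base[paste0("effect_", seq_len(nF))] <- replicate(nF, numeric(0),
                                                      simplify = FALSE)
    return(base)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
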