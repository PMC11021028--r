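#' Simulate a regularly spaced marker map
#'
#' Builds a marker grid mimicking the genotyping grid of a multiparental
#' panel such as the DSPR, where founder ancestry probabilities are
#' available at evenly spaced physical positions (every 10 kb in the DSPR).
#' Markers are placed at 0, `spacing_bp`, 2 x `spacing_bp`, ... up to
#' `chrom_length_bp` on each chromosome, and genetic positions are obtained
#' from a constant recombination-rate conversion.
#'
#' @param n_chromosomes Number of chromosomes to simulate.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param spacing_bp Distance between adjacent markers in base pairs.
#' @param cM_per_Mb Constant genetic-to-physical conversion rate
#'   (centiMorgan per megabase).
#' @return A `marker_map` data frame with columns `marker_id`, `chrom`,
#'   `pos_bp` and `pos_cM`, ordered by chromosome then position.
#' @examples
#' map <- simulate_marker_map(1, 1e5, 1e4, 2)
#' nrow(map)  # 11 markers at 0 ... 100 kb
#' @export
simulate_marker_map <- function(n_chromosomes, chrom_length_bp, spacing_bp,
                                cM_per_Mb) {
  if (n_chromosomes < 1 || chrom_length_bp <= 0 || spacing_bp <= 0 ||
      cM_per_Mb < 0) {
    stop_mpp("n_chromosomes >= 1, chrom_length_bp > 0, spacing_bp > 0 and cM_per_Mb >= 0 are required",
             "mppeqtl_invalid_argument")
  }
  pos <- seq(0L, as.integer(chrom_length_bp), by = as.integer(spacing_bp))
  maps <- lapply(seq_len(n_chromosomes), function(ch) {
    data.frame(
      marker_id = sprintf("c%d_m%05d", ch, seq_along(pos)),
      chrom = as.character(ch),
      pos_bp = pos,
      pos_cM = pos * cM_per_Mb / 1e6,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  map
}

#' Validate a marker map
#'
#' Checks uniqueness of marker ids and, within each chromosome, strictly
#' increasing physical positions with non-decreasing genetic positions.
#'
#' @param map A data frame with columns `marker_id`, `chrom`, `pos_bp`,
#'   `pos_cM`.
#' @return The validated map, invisibly, with class `marker_map`.
#' @export
validate_marker_map <- function(map) {
  need <- c("marker_id", "chrom", "pos_bp", "pos_cM")
  if (!all(need %in% names(map))) {
    stop_mpp(paste("marker map must have columns", paste(need, collapse = ", ")),
             "mppeqtl_invalid_argument")
  }
  if (anyDuplicated(map$marker_id)) {
    stop_mpp("duplicate marker_id in marker map", "mppeqtl_validation_error")
  }
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (any(diff(sub$pos_bp) <= 0)) {
      stop_mpp(sprintf("markers on chromosome %s not strictly increasing in bp", ch),
               "mppeqtl_validation_error")
    }
    if (any(diff(sub$pos_cM) < 0)) {
      stop_mpp(sprintf("markers on chromosome %s decreasing in cM", ch),
               "mppeqtl_validation_error")
    }
  }
  if (!inherits(map, "marker_map")) class(map) <- c("marker_map", class(map))
  invisible(map)
}

#' Simulate gene annotations on a marker map
#'
#' Places genes uniformly at random along the chromosomes of a marker map.
#' Genetic (cM) midpoint positions are interpolated from the map, as needed
#' for cis/trans classification of eQTL peaks.
#'
#' @param map A `marker_map`.
#' @param n_genes Number of genes.
#' @param gene_length_bp Fixed gene length in bp.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `gene_annotation` data frame with columns `gene_id`, `chrom`,
#'   `start_bp`, `end_bp`, `pos_cM` (interpolated midpoint).
#' @export
simulate_gene_annotation <- function(map, n_genes, gene_length_bp = 2000L,
                                     seed = 1L) {
  validate_marker_map(map)
  if (n_genes < 1) stop_mpp("n_genes must be >= 1", "mppeqtl_invalid_argument")
  set.seed(seed)
  chroms <- unique(map$chrom)
  chrom <- sample(chroms, n_genes, replace = TRUE)
  ann <- lapply(seq_len(n_genes), function(i) {
    sub <- map[map$chrom == chrom[i], ]
    lo <- min(sub$pos_bp)
    hi <- max(sub$pos_bp) - gene_length_bp
    start <- floor(runif(1, lo, max(lo + 1, hi)))
    data.frame(chrom = chrom[i], start_bp = start,
               end_bp = start + gene_length_bp, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, ann)
  ann <- ann[order(ann$chrom, ann$start_bp), , drop = FALSE]
  ann <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)), ann,
                    stringsAsFactors = FALSE)
  ann$pos_cM <- interpolate_cM(map, ann$chrom, (ann$start_bp + ann$end_bp) / 2)
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Interpolate genetic positions from a marker map
#'
#' Linear interpolation of cM coordinates at arbitrary bp positions;
#' positions beyond the terminal markers are clamped to the ends.
#'
#' @param map A `marker_map`.
#' @param chrom Character vector of chromosome names.
#' @param pos_bp Numeric vector of physical positions, same length.
#' @return Numeric vector of cM positions.
#' @export
interpolate_cM <- function(map, chrom, pos_bp) {
  stopifnot(length(chrom) == length(pos_bp))
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) == 0) {
      stop_mpp(sprintf("chromosome %s absent from marker map", ch),
               "mppeqtl_invalid_reference")
    }
    idx <- chrom == ch
    out[idx] <- approx(sub$pos_bp, sub$pos_cM, xout = pos_bp[idx],
                       rule = 2)$y
  }
  out
}
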