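# On-disk formats: tab-separated text with a '#'-prefixed header line.
# bp coordinates are 1-based inclusive in annotation files (GFF3
# convention); the simulator's internal marker grid starts at 0 and is
# written as-is. cM positions are reals.

#' Write a data frame as TSV with a '#'-prefixed header
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  df <- read.table(path, sep = "\t", skip = 1, header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "",
                   quote = "")
  names(df) <- strsplit(header, "\t")[[1]]
  df
}

#' Write / read a marker map
#'
#' Columns: `marker_id`, `chrom`, `pos_bp`, `pos_cM`.
#' @param map A `marker_map`.
#' @param path File path.
#' @export
write_marker_map <- function(map, path) write_tsv(as.data.frame(map), path)

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  map <- read_tsv(path)
  map$chrom <- as.character(map$chrom)
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  map
}

#' Write / read founder probabilities (long format)
#'
#' Long TSV with columns `strain`, `marker`, `founder_index`,
#' `probability`. The reader validates the range and sum-to-one
#' invariants and, when a marker map is supplied, orders markers to match
#' it.
#'
#' @param probs A `founder_probs`.
#' @param path File path.
#' @param map Optional `marker_map` fixing the marker order.
#' @export
write_founder_probs <- function(probs, path) {
  P <- probs$P
  d <- dim(P)
  long <- data.frame(
    strain = rep(probs$strains, times = d[2] * d[3]),
    marker = rep(rep(probs$markers, each = d[1]), times = d[3]),
    founder_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    probability = as.vector(P))
  write_tsv(long, path)
}

#' @rdname write_founder_probs
#' @export
read_founder_probs <- function(path, map = NULL) {
  long <- read_tsv(path)
  need <- c("strain", "marker", "founder_index", "probability")
  if (!all(need %in% names(long))) {
    stop_mpp(paste("founder probability file needs columns",
                   paste(need, collapse = ", ")),
             "mppeqtl_invalid_argument")
  }
  bad <- which(long$probability < 0 | long$probability > 1)
  if (length(bad) > 0) {
    stop_mpp(sprintf("probability outside [0,1] at data row %d (strain %s, marker %s)",
                     bad[1], long$strain[bad[1]], long$marker[bad[1]]),
             "mppeqtl_validation_error")
  }
  strains <- unique(long$strain)
  markers <- unique(long$marker)
  if (!is.null(map)) {
    unknown <- setdiff(markers, map$marker_id)
    if (length(unknown) > 0) {
      stop_mpp(paste("markers absent from map:",
                     paste(unknown, collapse = ", ")),
               "mppeqtl_invalid_reference")
    }
    markers <- map$marker_id[map$marker_id %in% markers]
  }
  nF <- max(long$founder_index)
  P <- array(NA_real_, c(length(strains), length(markers), nF))
  si <- match(long$strain, strains)
  mi <- match(long$marker, markers)
  P[cbind(si, mi, long$founder_index)] <- long$probability
  if (anyNA(P)) {
    stop_mpp("incomplete founder probability table",
             "mppeqtl_validation_error")
  }
  founder_probs(P, strains, markers)
}

#' Write / read a count matrix
#'
#' Genes in rows (first column `gene_id`), samples in columns.
#' @param counts Integer matrix with dimnames.
#' @param path File path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) {
    stop_mpp("negative counts", "mppeqtl_validation_error")
  }
  m
}

#' Write / read a sample table
#' @param samples A `sample_table`.
#' @param path File path.
#' @export
write_sample_table <- function(samples, path) {
  write_tsv(as.data.frame(samples), path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  df <- read_tsv(path)
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write / read a simulation truth table
#' @param truth A `simulation_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) write_tsv(as.data.frame(truth), path)

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read_tsv(path)
  class(df) <- c("simulation_truth", "data.frame")
  df
}

#' Write / read a trait matrix
#'
#' Genes in rows, strains in columns; dataset label and provenance stored
#' in companion attributes are written to a sidecar JSON when `sidecar`
#' is `TRUE`.
#'
#' @param traits A `trait_matrix`.
#' @param path File path.
#' @param sidecar Write `<path>.json` with dataset, provenance and PC
#'   selection.
#' @export
write_trait_matrix <- function(traits, path, sidecar = TRUE) {
  df <- data.frame(gene_id = rownames(traits), as.data.frame(unclass(traits)),
                   check.names = FALSE)
  write_tsv(df, path)
  if (sidecar) {
    meta <- list(dataset = attr(traits, "dataset"),
                 provenance = attr(traits, "provenance"),
                 pcs_removed = attr(traits, "pcs_removed"),
                 var_share = attr(traits, "var_share"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(m, "dataset") <- meta$dataset
    attr(m, "provenance") <- meta$provenance
    attr(m, "pcs_removed") <- meta$pcs_removed
  }
  class(m) <- c("trait_matrix", "matrix", "array")
  m
}

#' Read gene annotation from TSV or GFF3
#'
#' TSV needs columns `gene_id`, `chrom`, `start_bp`, `end_bp`; GFF3 files
#' (gene features) are read with `rtracklayer::import`. When a marker map
#' is supplied, midpoint cM positions are interpolated and attached.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gff3"` (guessed from the extension by
#'   default).
#' @param map Optional `marker_map` for cM interpolation.
#' @return A `gene_annotation` data frame.
#' @export
read_gene_annotation <- function(path, format = NULL, map = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop_mpp("rtracklayer is required to read GFF3",
               "mppeqtl_invalid_argument")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ann <- data.frame(gene_id = as.character(gr$ID),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start_bp = GenomicRanges::start(gr),
                      end_bp = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  } else {
    ann <- read_tsv(path)
    ann$chrom <- as.character(ann$chrom)
  }
  need <- c("gene_id", "chrom", "start_bp", "end_bp")
  if (!all(need %in% names(ann))) {
    stop_mpp(paste("gene annotation needs columns",
                   paste(need, collapse = ", ")),
             "mppeqtl_invalid_argument")
  }
  if (any(ann$start_bp > ann$end_bp)) {
    stop_mpp("gene with start > end", "mppeqtl_validation_error")
  }
  if (!is.null(map) && !"pos_cM" %in% names(ann)) {
    ann$pos_cM <- interpolate_cM(map, ann$chrom,
                                 (ann$start_bp + ann$end_bp) / 2)
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write gene annotation
#' @param genes A `gene_annotation`.
#' @param path File path.
#' @export
write_gene_annotation <- function(genes, path) {
  write_tsv(as.data.frame(genes), path)
}

#' Write / read a peak table
#' @param peaks Peak table from [peak_table()].
#' @param path File path.
#' @export
write_peaks <- function(peaks, path) write_tsv(peaks, path)

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- read_tsv(path)
  df$chrom <- as.character(df$chrom)
  df
}
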