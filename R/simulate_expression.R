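#' Build a factorial sample table
#'
#' Crosses strains with tissues and treatments, mirroring a design in which
#' every strain contributes one library per tissue x treatment cell.
#' Strains are split evenly into resistance classes (alternating) and into
#' `n_pools` sequencing pools (consecutive strain blocks, crossing tissues
#' and resistance classes) standing for plate / library-pool / flowcell
#' technical batches. Block assignment keeps the pooling covariate
#' estimable alongside the tissue x treatment x resistance factorial.
#'
#' @param strains Character vector of strain ids.
#' @param tissues,treatments Factor levels of the design.
#' @param n_pools Number of pooling batches per tissue.
#' @return A `sample_table` data frame with columns `sample_id`, `strain`,
#'   `tissue`, `treatment`, `resistance_class`, `pool`.
#' @export
make_sample_table <- function(strains, tissues = c("head", "gut"),
                              treatments = c("control", "copper"),
                              n_pools = 4) {
  n <- length(strains)
  resistance <- rep(c("resistant", "sensitive"), length.out = n)
  names(resistance) <- strains
  pool_of <- rep(seq_len(n_pools), each = ceiling(n / n_pools),
                 length.out = n)
  names(pool_of) <- strains
  tab <- expand.grid(strain = strains, tissue = tissues,
                     treatment = treatments, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  tab$resistance_class <- resistance[tab$strain]
  tab$pool <- sprintf("p%d", pool_of[tab$strain])
  tab$sample_id <- sprintf("%s_%s_%s", tab$strain, tab$tissue, tab$treatment)
  tab <- tab[, c("sample_id", "strain", "tissue", "treatment",
                 "resistance_class", "pool")]
  rownames(tab) <- NULL
  class(tab) <- c("sample_table", "data.frame")
  tab
}

#' Plant eQTL into a simulation truth table
#'
#' Chooses target genes and causal markers and draws mean-centred founder
#' effect vectors, producing the ground-truth specification consumed by
#' [simulate_expression()]. Cis eQTL are placed at the marker nearest the
#' gene midpoint; trans eQTL at a marker on another chromosome or at least
#' `trans_min_cM` away from the gene.
#'
#' @param genes A `gene_annotation` data frame.
#' @param map A `marker_map`.
#' @param n_cis,n_trans Number of cis and trans eQTL to plant (distinct
#'   target genes).
#' @param effect_sd Standard deviation (log2 units) of founder effects
#'   before centring.
#' @param acts_in_tissue One of `"head"`, `"gut"`, `"both"`.
#' @param acts_in_treatment One of `"control"`, `"copper"`, `"both"`,
#'   `"differential"` (an effect present only under copper, a pure
#'   genotype-by-treatment architecture that leaves control expression
#'   free of genetic signal).
#' @param n_founders Number of founders.
#' @param trans_min_cM Minimum gene-marker distance for a trans eQTL.
#' @param seed Integer seed.
#' @return A `simulation_truth` data frame with columns `target_gene`,
#'   `eqtl_marker`, `acts_in_tissue`, `acts_in_treatment`,
#'   `expected_class` and `effect_1` ... `effect_F`.
#' @export
plant_eqtl <- function(genes, map, n_cis, n_trans, effect_sd = 0.35,
                       acts_in_tissue = "both", acts_in_treatment = "both",
                       n_founders = 8, trans_min_cM = 10, seed = 1L) {
  validate_marker_map(map)
  set.seed(seed)
  n <- n_cis + n_trans
  if (n > nrow(genes)) {
    stop_mpp("more planted eQTL than genes", "mppeqtl_invalid_argument")
  }
  if (n == 0) {
    truth <- data.frame(target_gene = character(0),
                        eqtl_marker = character(0),
                        acts_in_tissue = character(0),
                        acts_in_treatment = character(0),
                        expected_class = character(0),
                        stringsAsFactors = FALSE)
    truth[paste0("effect_", seq_len(n_founders))] <-
      replicate(n_founders, numeric(0), simplify = FALSE)
    class(truth) <- c("simulation_truth", "data.frame")
    return(truth)
  }
  targets <- sample(genes$gene_id, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes[genes$gene_id == targets[i], ]
    cls <- if (i <= n_cis) "cis" else "trans"
    if (cls == "cis") {
      sub <- map[map$chrom == g$chrom, ]
      mk <- sub$marker_id[which.min(abs(sub$pos_cM - g$pos_cM))]
    } else {
      far <- map$chrom != g$chrom | abs(map$pos_cM - g$pos_cM) >= trans_min_cM
      if (!any(far)) {
        stop_mpp("no marker far enough from gene for a trans eQTL",
                 "mppeqtl_invalid_argument")
      }
      mk <- sample(map$marker_id[far], 1)
    }
    eff <- rnorm(n_founders, 0, effect_sd)
    eff <- eff - mean(eff)
    row <- data.frame(target_gene = g$gene_id, eqtl_marker = mk,
                      acts_in_tissue = acts_in_tissue,
                      acts_in_treatment = acts_in_treatment,
                      expected_class = cls, stringsAsFactors = FALSE)
    row[paste0("effect_", seq_len(n_founders))] <- as.list(eff)
    rows[[i]] <- row
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  class(truth) <- c("simulation_truth", "data.frame")
  truth
}

# internal: F-vector of planted effects from a truth row
truth_effects <- function(truth_row) {
  as.numeric(truth_row[grep("^effect_", names(truth_row))])
}

#' Simulate RNA-seq counts with planted eQTL
#'
#' Generates negative-binomial read counts for all samples in a sample
#' table. Per sample and gene, the expected count is
#' `2^(baseline_g + genetic + batch) * library_factor`, where `genetic` is
#' the sum over planted eQTL (acting in that sample's tissue/treatment) of
#' the founder-effect vector dotted with the strain's founder dosage at the
#' causal marker, and `batch` is an additive log2 shift shared by all genes
#' of a sequencing pool. eQTL with `acts_in_treatment = "differential"`
#' (synonym: `"copper"`) act only under the copper treatment, driving the
#' copper-control response while leaving control expression free of
#' genetic signal.
#'
#' @param truth A `simulation_truth` table (may have zero rows).
#' @param probs A `founder_probs` object covering all strains in `samples`.
#' @param samples A `sample_table`.
#' @param gene_ids Character vector of gene ids (must contain every truth
#'   target gene).
#' @param baseline_log2_mean Mean baseline log2 expression.
#' @param baseline_sd Per-gene spread of baseline log2 expression.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param batch_sd Standard deviation of per-pool log2 shifts.
#' @param library_size_range Length-2 vector; per-sample relative library
#'   size factors are drawn uniformly from this range.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Integer count matrix, genes in rows, samples in columns.
#' @export
simulate_expression <- function(truth, probs, samples, gene_ids,
                                baseline_log2_mean = 6, baseline_sd = 1.5,
                                nb_dispersion = 0.05, batch_sd = 0.3,
                                library_size_range = c(0.7, 1.3),
                                seed = 1L) {
  if (nb_dispersion <= 0) {
    stop_mpp("nb_dispersion must be > 0", "mppeqtl_invalid_argument")
  }
  if (nrow(truth) > 0) {
    if (!all(truth$target_gene %in% gene_ids)) {
      stop_mpp("truth target gene absent from gene_ids",
               "mppeqtl_invalid_reference")
    }
    if (!all(truth$eqtl_marker %in% probs$markers)) {
      stop_mpp("truth eQTL marker absent from founder probabilities",
               "mppeqtl_invalid_reference")
    }
  }
  if (!all(samples$strain %in% probs$strains)) {
    stop_mpp("sample strain absent from founder probabilities",
             "mppeqtl_invalid_reference")
  }
  set.seed(seed)
  G <- length(gene_ids); n <- nrow(samples)
  baseline <- baseline_log2_mean + rnorm(G, 0, baseline_sd)
  pools <- unique(samples$pool)
  pool_shift <- rnorm(length(pools), 0, batch_sd)
  names(pool_shift) <- pools
  lib <- runif(n, library_size_range[1], library_size_range[2])

  log2mu <- matrix(baseline, G, n, dimnames = list(gene_ids, samples$sample_id))
  log2mu <- sweep(log2mu, 2, pool_shift[samples$pool], `+`)
  s_idx <- match(samples$strain, probs$strains)
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    eff <- truth_effects(tr)
    dose <- probs_at_marker(probs, tr$eqtl_marker) %*% eff  # per strain
    gi <- match(tr$target_gene, gene_ids)
    in_tissue <- tr$acts_in_tissue == "both" | samples$tissue == tr$acts_in_tissue
    mult <- switch(tr$acts_in_treatment,
      both = as.numeric(in_tissue),
      control = as.numeric(in_tissue & samples$treatment == "control"),
      copper = ,
      differential = as.numeric(in_tissue & samples$treatment == "copper"),
      stop_mpp(sprintf("unknown acts_in_treatment '%s'", tr$acts_in_treatment),
               "mppeqtl_invalid_argument"))
    log2mu[gi, ] <- log2mu[gi, ] + dose[s_idx] * mult
  }
  mu <- sweep(2^log2mu, 2, lib, `*`)
  counts <- matrix(rnbinom(G * n, mu = mu, size = 1 / nb_dispersion), G, n,
                   dimnames = dimnames(log2mu))
  storage.mode(counts) <- "integer"
  counts
}

#' Expected noise-free log2 means of a simulation
#'
#' Returns the genetic + baseline log2 mean surface (no batch, no library
#' scaling, no counting noise) for a truth table, useful for verifying
#' that regression on founder dosage recovers planted effects.
#'
#' @inheritParams simulate_expression
#' @param baseline Per-gene baseline log2 values (default all zero).
#' @return Matrix genes x samples of log2 means.
#' @export
expected_log2_means <- function(truth, probs, samples, gene_ids,
                                baseline = NULL) {
  G <- length(gene_ids); n <- nrow(samples)
  if (is.null(baseline)) baseline <- numeric(G)
  log2mu <- matrix(baseline, G, n, dimnames = list(gene_ids, samples$sample_id))
  s_idx <- match(samples$strain, probs$strains)
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    eff <- truth_effects(tr)
    dose <- probs_at_marker(probs, tr$eqtl_marker) %*% eff
    gi <- match(tr$target_gene, gene_ids)
    in_tissue <- tr$acts_in_tissue == "both" | samples$tissue == tr$acts_in_tissue
    mult <- switch(tr$acts_in_treatment,
      both = as.numeric(in_tissue),
      control = as.numeric(in_tissue & samples$treatment == "control"),
      copper = ,
      differential = as.numeric(in_tissue & samples$treatment == "copper"))
    log2mu[gi, ] <- log2mu[gi, ] + dose[s_idx] * mult
  }
  log2mu
}
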