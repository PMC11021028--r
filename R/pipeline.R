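#' Build a pipeline configuration
#'
#' Collects all tunable parameters of the pipeline with the study's
#' defaults: gene filter 10 counts in 47 samples, PC variance threshold
#' 2%, 1000 permutations at the 95% threshold, 3-LOD-drop intervals, and
#' 1.5 cM windows for cis classification and cross-dataset sharing. A
#' seed is mandatory because permutation thresholds (and any simulated
#' inputs) are stochastic.
#'
#' @param datasets Dataset labels to run (`"<tissue>-<trait>"`).
#' @param seed Integer seed.
#' @param min_count,min_samples Gene-filter parameters.
#' @param var_fraction PC variance-share threshold.
#' @param n_perm,alpha Permutation-threshold parameters.
#' @param lod_drop Support-interval drop.
#' @param cis_window_cM Cis classification window.
#' @param window_cM Sharing window.
#' @param paths Named list of input paths (`counts`, `samples`, `map`,
#'   `probs`, `genes`), or `NULL` when inputs are passed in memory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(datasets = c("head-control", "head-copper",
                                         "head-response", "gut-control",
                                         "gut-copper", "gut-response"),
                            seed,
                            min_count = 10, min_samples = 47,
                            var_fraction = 0.02, n_perm = 1000,
                            alpha = 0.05, lod_drop = 3.0,
                            cis_window_cM = 1.5, window_cM = 1.5,
                            paths = NULL) {
  if (missing(seed)) {
    stop_mpp("a seed is mandatory", "mppeqtl_invalid_argument")
  }
  structure(list(datasets = datasets, seed = as.integer(seed),
                 min_count = min_count, min_samples = min_samples,
                 var_fraction = var_fraction, n_perm = n_perm,
                 alpha = alpha, lod_drop = lod_drop,
                 cis_window_cM = cis_window_cM, window_cM = window_cM,
                 paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Simulate a complete DSPR-like study
#'
#' One-call generator for the desk-scale study the pipeline is exercised
#' on: a 10-kb marker grid, recombinant-inbred founder mosaics with
#' smoothed ancestry probabilities, gene annotations, a factorial sample
#' table (strains x 2 tissues x 2 treatments with pooling batches), a
#' planted-eQTL truth table and negative-binomial counts.
#'
#' @param n_strains Number of RIL strains.
#' @param n_chromosomes,chrom_length_bp,spacing_bp,cM_per_Mb Marker-map
#'   parameters.
#' @param n_genes Number of genes.
#' @param n_founders Number of founders.
#' @param truth A `simulation_truth` table, or `NULL` to plant
#'   `n_cis` + `n_trans` eQTL with effect spread `effect_sd` acting in
#'   `acts_in_tissue` / `acts_in_treatment`.
#' @param n_cis,n_trans,effect_sd,acts_in_tissue,acts_in_treatment Planting
#'   parameters used when `truth` is `NULL`.
#' @param nb_dispersion,batch_sd,baseline_log2_mean,baseline_sd,library_size_range
#'   Count-model parameters.
#' @param expected_crossovers_per_chrom,prob_smoothing Genome-mosaic
#'   parameters.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return List with `map`, `genes`, `probs`, `assignments`, `samples`,
#'   `truth`, `counts`.
#' @export
simulate_study <- function(n_strains = 96, n_chromosomes = 2,
                           chrom_length_bp = 1.5e6, spacing_bp = 1e4,
                           cM_per_Mb = 20, n_genes = 500, n_founders = 8,
                           truth = NULL, n_cis = 10, n_trans = 10,
                           effect_sd = 0.35, acts_in_tissue = "both",
                           acts_in_treatment = "both",
                           nb_dispersion = 0.05, batch_sd = 0.3,
                           baseline_log2_mean = 6, baseline_sd = 1.5,
                           library_size_range = c(0.7, 1.3),
                           expected_crossovers_per_chrom = 2,
                           prob_smoothing = 0.05, seed = 1L) {
  map <- simulate_marker_map(n_chromosomes, chrom_length_bp, spacing_bp,
                             cM_per_Mb)
  genes <- simulate_gene_annotation(map, n_genes, seed = seed + 1L)
  gen <- simulate_ril_genomes(map, n_strains, n_founders = n_founders,
                              expected_crossovers_per_chrom =
                                expected_crossovers_per_chrom,
                              prob_smoothing = prob_smoothing,
                              seed = seed + 2L)
  samples <- make_sample_table(gen$probs$strains)
  if (is.null(truth)) {
    truth <- plant_eqtl(genes, map, n_cis = n_cis, n_trans = n_trans,
                        effect_sd = effect_sd,
                        acts_in_tissue = acts_in_tissue,
                        acts_in_treatment = acts_in_treatment,
                        n_founders = n_founders, seed = seed + 3L)
  }
  counts <- simulate_expression(truth, gen$probs, samples, genes$gene_id,
                                baseline_log2_mean = baseline_log2_mean,
                                baseline_sd = baseline_sd,
                                nb_dispersion = nb_dispersion,
                                batch_sd = batch_sd,
                                library_size_range = library_size_range,
                                seed = seed + 4L)
  list(map = map, genes = genes, probs = gen$probs,
       assignments = gen$assignments, samples = samples, truth = truth,
       counts = counts)
}

#' Run the end-to-end eQTL pipeline
#'
#' Executes filter -> trait preparation -> Haley-Knott scans with
#' permutation thresholds -> peak calling/classification for every
#' configured dataset, then cross-dataset sharing for the standard
#' comparisons (between tissues within treatment and between treatments
#' within tissue). Writes per-dataset trait matrices, threshold tables and
#' peak tables, sharing reports, a stage log with the number of genes and
#' peaks surviving each step, and a manifest recording parameters and
#' seeds. Reruns with the same config and inputs are bit-identical.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param inputs Named list with `counts`, `samples`, `map`, `probs`,
#'   `genes`; when `NULL`, read from `config$paths`.
#' @return Invisibly, a list with per-dataset peak tables, sharing
#'   reports and the manifest.
#' @export
run_pipeline <- function(config, out_dir, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs)) {
    p <- config$paths
    need <- c("counts", "samples", "map", "probs", "genes")
    missing_p <- setdiff(need, names(p))
    missing_f <- names(p)[!vapply(p, file.exists, logical(1))]
    if (length(missing_p) > 0 || length(missing_f) > 0) {
      stop_mpp(paste("missing inputs:",
                     paste(c(missing_p, missing_f), collapse = ", ")),
               "mppeqtl_invalid_argument")
    }
    map <- read_marker_map(p$map)
    inputs <- list(counts = read_counts(p$counts),
                   samples = read_sample_table(p$samples),
                   map = map,
                   probs = read_founder_probs(p$probs, map = map),
                   genes = read_gene_annotation(p$genes, map = map))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  counts <- filter_low_expression(inputs$counts,
                                  min_count = config$min_count,
                                  min_samples = config$min_samples)
  log_add("filter: %d of %d genes retained", nrow(counts),
          nrow(inputs$counts))
  genes <- inputs$genes
  if (!"pos_cM" %in% names(genes)) {
    genes$pos_cM <- interpolate_cM(inputs$map, genes$chrom,
                                   (genes$start_bp + genes$end_bp) / 2)
  }
  peaks <- list()
  for (ds in config$datasets) {
    traits <- prepare_trait_matrix(counts, inputs$samples, ds,
                                   var_fraction = config$var_fraction,
                                   alpha = config$alpha)
    log_add("%s: %d genes x %d strains; PCs removed: %s", ds,
            nrow(traits), ncol(traits),
            paste(attr(traits, "pcs_removed"), collapse = ","))
    scan <- scan_all(traits, inputs$probs)
    thr <- permutation_thresholds(traits, inputs$probs,
                                  n_perm = config$n_perm,
                                  alpha = config$alpha,
                                  seed = config$seed)
    pk <- peak_table(scan, thr, inputs$map, genes, traits, inputs$probs,
                     lod_drop = config$lod_drop,
                     cis_window_cM = config$cis_window_cM)
    log_add("%s: %d peaks (%d cis, %d trans) for %d genes", ds, nrow(pk),
            sum(pk$class == "cis"), sum(pk$class == "trans"),
            length(unique(pk$gene)))
    write_trait_matrix(traits, file.path(out_dir, paste0(ds, "_traits.tsv")))
    write_tsv(data.frame(gene = names(thr), threshold = unname(thr)),
              file.path(out_dir, paste0(ds, "_thresholds.tsv")))
    write_peaks(pk, file.path(out_dir, paste0(ds, "_peaks.tsv")))
    peaks[[ds]] <- pk
  }
  comparisons <- standard_comparisons(config$datasets)
  sharing <- list()
  for (cmp in comparisons) {
    rep_name <- paste(cmp[1], "vs", cmp[2])
    sh <- match_shared_eqtl(peaks[[cmp[1]]], peaks[[cmp[2]]],
                            window_cM = config$window_cM)
    sharing[[rep_name]] <- sh
    write_tsv(sh$matched,
              file.path(out_dir, sprintf("sharing_%s_vs_%s.tsv",
                                         cmp[1], cmp[2])))
    log_add("sharing %s: %d matched, %d unique to %s, %d unique to %s",
            rep_name, nrow(sh$matched), length(sh$unique_a), cmp[1],
            length(sh$unique_b), cmp[2])
  }
  manifest <- list(
    package = "mppeqtl",
    version = as.character(utils::packageVersion("mppeqtl")),
    seed = config$seed,
    parameters = config[c("min_count", "min_samples", "var_fraction",
                          "n_perm", "alpha", "lod_drop", "cis_window_cM",
                          "window_cM")],
    datasets = config$datasets,
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(peaks = peaks, sharing = sharing, manifest = manifest))
}

# internal: the study's standard dataset comparisons — between tissues
# within treatment, and between treatments within tissue
standard_comparisons <- function(datasets) {
  cmps <- list(c("head-control", "gut-control"),
               c("head-copper", "gut-copper"),
               c("head-response", "gut-response"),
               c("head-control", "head-copper"),
               c("gut-control", "gut-copper"))
  Filter(function(cmp) all(cmp %in% datasets), cmps)
}
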