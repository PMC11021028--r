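#' Construct a founder-probability object
#'
#' Container for additive founder-ancestry probabilities: for every strain
#' and marker, a probability vector over the founders giving the likelihood
#' that the region descends from each founder.
#'
#' @param P Numeric array `strain x marker x founder`.
#' @param strains Character vector of strain ids (rows of `P`).
#' @param markers Character vector of marker ids (second dimension of `P`).
#' @return A `founder_probs` object.
#' @export
founder_probs <- function(P, strains, markers) {
  stopifnot(length(dim(P)) == 3, dim(P)[1] == length(strains),
            dim(P)[2] == length(markers))
  dimnames(P) <- list(strains, markers, paste0("F", seq_len(dim(P)[3])))
  obj <- structure(list(strains = strains, markers = markers, P = P),
                   class = "founder_probs")
  validate_founder_probs(obj)
  obj
}

#' Validate founder probabilities
#'
#' Checks that every probability lies in `[0, 1]` and that, for each
#' strain x marker, the probabilities over founders sum to one within
#' `1e-9`.
#'
#' @param probs A `founder_probs` object.
#' @return The object, invisibly.
#' @export
validate_founder_probs <- function(probs) {
  P <- probs$P
  if (any(P < 0) || any(P > 1)) {
    bad <- which(P < 0 | P > 1, arr.ind = TRUE)[1, ]
    stop_mpp(sprintf("probability outside [0,1] at strain %s, marker %s",
                     probs$strains[bad[1]], probs$markers[bad[2]]),
             "mppeqtl_validation_error")
  }
  sums <- apply(P, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    bad <- which(abs(sums - 1) > 1e-9, arr.ind = TRUE)[1, ]
    stop_mpp(sprintf("founder probabilities do not sum to 1 for strain %s, marker %s",
                     probs$strains[bad[1]], probs$markers[bad[2]]),
             "mppeqtl_validation_error")
  }
  invisible(probs)
}

#' @export
print.founder_probs <- function(x, ...) {
  cat(sprintf("founder_probs: %d strains x %d markers x %d founders\n",
              length(x$strains), length(x$markers), dim(x$P)[3]))
  invisible(x)
}

#' Extract the strain x founder probability matrix at one marker
#'
#' @param probs A `founder_probs` object.
#' @param marker A marker id.
#' @return Numeric matrix, strains in rows, founders in columns.
#' @export
probs_at_marker <- function(probs, marker) {
  j <- match(marker, probs$markers)
  if (is.na(j)) {
    stop_mpp(sprintf("marker %s not in founder probabilities", marker),
             "mppeqtl_invalid_reference")
  }
  probs$P[, j, , drop = TRUE]
}

#' Simulate recombinant inbred genomes as founder mosaics
#'
#' Each strain's chromosome is a mosaic of founder blocks, emulating the
#' genome structure of advanced-intercross recombinant inbred lines. The
#' number of breakpoints per strain-chromosome is drawn Poisson with mean
#' `expected_crossovers_per_chrom`, breakpoint positions are uniform in cM,
#' and each block's founder differs from its neighbour (drawn uniformly
#' from the remaining founders). Ancestry probabilities are smoothed
#' one-hot vectors: `1 - prob_smoothing` on the true founder and
#' `prob_smoothing / (F - 1)` on each other founder, emulating residual
#' ancestry-assignment uncertainty.
#'
#' @param map A `marker_map`.
#' @param n_strains Number of strains.
#' @param n_founders Number of founders (>= 2; DSPR-like panels have 8).
#' @param expected_crossovers_per_chrom Poisson mean of breakpoints per
#'   strain-chromosome.
#' @param prob_smoothing Smoothing mass in `[0, 1)` spread over the
#'   non-ancestral founders.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with components `assignments` (integer matrix
#'   strain x marker of true founder indices), `probs` (a `founder_probs`)
#'   and `n_breakpoints` (integer matrix strain x chromosome of drawn
#'   crossover counts).
#' @export
simulate_ril_genomes <- function(map, n_strains, n_founders = 8,
                                 expected_crossovers_per_chrom = 2,
                                 prob_smoothing = 0.05, seed = 1L) {
  validate_marker_map(map)
  if (n_founders < 2) {
    stop_mpp("n_founders must be >= 2", "mppeqtl_invalid_argument")
  }
  if (prob_smoothing < 0 || prob_smoothing >= 1) {
    stop_mpp("prob_smoothing must be in [0, 1)", "mppeqtl_invalid_argument")
  }
  set.seed(seed)
  chroms <- unique(map$chrom)
  strains <- sprintf("s%03d", seq_len(n_strains))
  n_mark <- nrow(map)
  assignments <- matrix(NA_integer_, n_strains, n_mark,
                        dimnames = list(strains, map$marker_id))
  n_bp <- matrix(0L, n_strains, length(chroms),
                 dimnames = list(strains, chroms))
  for (ci in seq_along(chroms)) {
    sub_idx <- which(map$chrom == chroms[ci])
    cm <- map$pos_cM[sub_idx]
    lo <- min(cm); hi <- max(cm)
    for (s in seq_len(n_strains)) {
      k <- rpois(1, expected_crossovers_per_chrom)
      n_bp[s, ci] <- k
      brk <- sort(runif(k, lo, hi))
      founders <- integer(k + 1)
      founders[1] <- sample.int(n_founders, 1)
      if (k > 0) {
        for (b in seq_len(k)) {
          # neighbouring blocks carry different founders so every
          # breakpoint is a real ancestry switch
          founders[b + 1] <- sample(setdiff(seq_len(n_founders), founders[b]), 1)
        }
      }
      block <- findInterval(cm, brk) + 1L
      assignments[s, sub_idx] <- founders[block]
    }
  }
  P <- array(prob_smoothing / (n_founders - 1),
             dim = c(n_strains, n_mark, n_founders))
  for (f in seq_len(n_founders)) {
    P[, , f][assignments == f] <- 1 - prob_smoothing
  }
  list(assignments = assignments,
       probs = founder_probs(P, strains, map$marker_id),
       n_breakpoints = n_bp)
}
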