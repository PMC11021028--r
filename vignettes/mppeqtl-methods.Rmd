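---
title: "Methods: multiparental eQTL mapping with mppeqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparental eQTL mapping with mppeqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the statistical machinery it
implements: the models, the tunable parameters and their defaults, what
the synthetic data generator does and does not emulate, and the numerical
and design choices made where more than one reasonable option existed.

## The mapping model

Each recombinant inbred strain of an 8-founder panel carries a genome
that is a mosaic of founder blocks. At every marker of a dense grid the
genotype state is summarized by an additive probability vector
$p_{s,m} \in [0,1]^8$, $\sum_f p_{s,m,f} = 1$: the probability that
strain $s$ inherited the region around marker $m$ from founder $f$.
Haley–Knott regression treats these probabilities as regression dosages.
For a trait $y$ (one value per strain), the full model at marker $m$ is
the ordinary least-squares fit of $y$ on the eight probability columns
with no separate intercept — the columns sum to one, so the intercept is
contained in their span — and the null model is intercept-only. The
evidence for a QTL is

$$\mathrm{LOD}(m) = \frac{n}{2}\,\log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1(m)}.$$

This is the standard LOD for Gaussian OLS; the package never writes a
likelihood explicitly. `scan_all()` evaluates all genes at all markers
through one orthonormal-basis decomposition per marker (QR, rank-aware),
so a whole permutation round is a single matrix product; batched results
are identical to per-gene `hk_scan()` calls, which the tests verify
against a brute-force two-model `lm()` oracle.

**Significance.** Thresholds are gene-specific: trait values are permuted
among strains, the genome-wide maximum LOD recorded per permutation, and
the empirical $(1-\alpha)$ quantile taken as the threshold (order
statistic $\lceil (1-\alpha)\,n_\mathrm{perm} \rceil$; $\alpha = 0.05$,
$n_\mathrm{perm} = 1000$ in routine use). By default one set of
permutation index vectors is shared across genes per round; this is what
makes a transcriptome-scale permutation run tractable, and each gene's
marginal threshold is unaffected. Per-gene independent permutations are
available with `share_permutations = FALSE`. Whether the original
approach shared index sets is unknowable from the outside; both
behaviours are provided, shared being the default.

**Peaks.** Candidate peaks are local maxima above threshold (plateau ties
break to the leftmost marker). Support intervals extend outward to the
first markers more than `lod_drop = 3` below the peak, including those
flanking markers, clipped at chromosome ends; a 3-LOD rather than 2-LOD
drop is used because 2-LOD intervals are too narrow at ~96 strains.
Additional peaks on a chromosome are accepted only when separated from
every accepted peak by a valley at least `lod_drop` below the lower of
the two — a documented choice mirroring interval-mapping practice, since
no published rule exists for multi-peak acceptance. Peaks whose
above-threshold run is a single marker, or whose position falls outside
their own interval, are removed; both phenomena concentrate near
chromosome ends at modest sample sizes.

**Cis versus trans.** A gene's genetic position is its midpoint in bp,
linearly interpolated on the marker map. A peak is cis when the gene lies
inside the support interval or within `cis_window_cM = 1.5` of either
boundary on the same chromosome; anything else, including any
other-chromosome peak, is trans. Because the rule works on the interval
boundaries, wider intervals yield more cis calls.

**Founder effects.** At the peak marker, effects are the OLS coefficients
of the trait on the eight probability columns, reported centred to mean
zero; percent variance is $100\,(1-\mathrm{RSS}_1/\mathrm{RSS}_0)$, which
obeys the algebraic identity
$100\,(1 - 10^{-2\,\mathrm{LOD}/n})$ with the peak LOD — the tests check
this to $10^{-9}$. Rank-deficient designs (a founder effectively absent)
fall back to the minimum-norm pseudo-inverse solution with a message.

## Trait preparation

Six datasets are prepared per study: {head, gut} × {control, copper,
response}. For control/copper the steps are, in order: gene filtering
(upstream), `log2(count + 1)` with column-wise quantile normalization to
the mean empirical distribution, removal of selected principal
components, and a per-gene rank-based inverse-normal transform
$\Phi^{-1}((r - 0.5)/n)$. For response, the first step is replaced by the
per-strain copper-minus-control difference, normalized on absolute
values with the sign reassigned afterwards so induction/repression
direction survives; zero differences map to exactly zero. Each
`trait_matrix` records its provenance so the composition order is
checkable.

PC selection takes components whose variance share exceeds
`var_fraction = 0.02`, plus any component associated with a known
technical covariate (one-way ANOVA for categorical, Pearson test for
numeric, at `alpha = 0.05` per PC × covariate, no multiplicity
correction). Choices the method description leaves open, fixed here:
the log offset is +1 (zeros are common in counts and in responses);
"quantile normalization" means column-wise normalization to the mean
distribution before PC removal but per-gene inverse-normal afterwards
(the standard for eQTL traits); ranking ties take average ranks;
response pairing requires both treatments per strain, and unpaired
strains are dropped with a warning.

A caveat that matters for small fixtures: with $G$ genes and $n$ strains
the largest *noise* eigenvalue of the sample covariance has share about
$(1+\sqrt{n/G})^2/n$. At transcriptome scale ($G \approx 10^4$,
$n \approx 96$) that is ~1.3%, safely under the 2% rule, so only real
structure is removed. At a few hundred genes the noise share itself
exceeds 2% and the rule starts discarding noise components that carry
signal degrees of freedom. The prep-sensitive end-to-end checks therefore
run at 2000 genes; this is a property of the selection rule, not of the
implementation.

## Differential expression

Counts are filtered by the rule "at least `min_count = 10` counts in at
least `min_samples = 47` samples" (47 being the per-three-way-cell sample
count in the motivating design) after dropping all-zero genes; both
numbers are parameters, so the opposite reading of the prose rule is one
flag away. TMM normalization follows the weighted trimmed mean of
M-values with trim fractions 0.30 (M) and 0.05 (A) and the reference
sample chosen by upper-quartile proximity to the mean; factors are
centred to multiply to one. The expression unit for modelling is log2
counts-per-million with TMM-scaled effective library sizes and a +0.5
offset — a trend-free moderated model on normalized counts, the simplest
faithful reading of the method description, which names neither a
precision-weight scheme nor an offset.

The gene-wise model is the full factorial
`~ tissue * treatment * resistance_class + pool`, fit by OLS with an
explicit rank check that names confounded columns. Variance moderation
estimates the prior degrees of freedom $d_0$ and prior variance $s_0^2$
by moment matching on log variances (digamma/trigamma inversion, Newton
iterations to $10^{-10}$, $d_0$ capped at $10^6$ as "infinite"; for
degenerate, near-identical variances the prior variance is the mean
observed variance). The moderated variance is
$(d_0 s_0^2 + d\,s_g^2)/(d_0 + d)$ and moderated $t$ uses $d + d_0$
degrees of freedom. Benjamini–Hochberg adjustment is the step-up rule.
The test suite cross-checks all three components against independent
implementations (`edgeR::calcNormFactors`, `limma::squeezeVar`,
`stats::p.adjust`) without using them in the pipeline itself.

In the generator's sample table, sequencing pools are consecutive strain
blocks crossing tissues and resistance classes. Nesting pools inside
tissue (as physical plates would be) makes the pooling term collinear
with the tissue effect and the factorial inestimable; block assignment
keeps the design full-rank while still exercising the batch-removal
machinery.

## The synthetic data generator

The generator's job is to produce data with the *structure* the pipeline
assumes, at desk scale, with known ground truth:

* **Marker grid** — evenly spaced markers (10 kb by default) with
  genetic positions from a constant cM/Mb rate. The genetic-map density
  of the real panel is not part of the published description, so
  `cM_per_Mb` is a free parameter (20 in the package's own checks,
  giving ~60 cM for a 3-Mb chromosome: compact but enough for clear
  cis/trans separation).
* **Genomes** — Poisson(`expected_crossovers_per_chrom = 2`) breakpoints
  uniform in cM, no interference; neighbouring blocks always change
  founder, so the drawn breakpoint count is the realized switch count.
  Ancestry probabilities are smoothed one-hot vectors
  (`prob_smoothing = 0.05` spread over the other founders) standing in
  for HMM posterior uncertainty; downstream algebra only needs valid
  probability vectors.
* **Counts** — negative binomial with a single dispersion
  (`nb_dispersion = 0.05`), per-gene baselines
  $\mathcal{N}(6, 1.5^2)$ in log2, a per-pool additive log2 batch shift
  (`batch_sd = 0.3`) shared by all genes of a pool, and per-sample
  library factors uniform in [0.7, 1.3].
* **Planted eQTL** — per target gene, a causal marker (nearest the gene
  for cis; ≥ 10 cM away or on another chromosome for trans) and a
  centred 8-vector of founder effects added to the log2 mean in the
  tissues/treatments where the eQTL acts. `effect_sd = 0.35` by default:
  with the default dispersion this puts the variance explained at a
  detected peak in the tens of percent, the range typical of reported
  eQTL; early experiments with multi-log2-unit effects made the planted
  genes dominate the trait covariance and the 2% PC rule then removed
  the genetic signal itself — an unrealistic regime, not a pipeline
  property. `acts_in_treatment = "differential"` means the effect is
  present only under copper (equivalently `"copper"`), the canonical
  genotype-by-treatment architecture: control expression carries no
  genetic signal while the copper-minus-control response does.

What the generator does **not** emulate: the linkage-disequilibrium
structure and allele frequencies of the real founders, sequence- or
read-level noise, gene-length and GC effects, count dispersion varying
with expression, or correlated expression modules. Passing tests
therefore demonstrate that the algorithms are correct and calibrated on
data satisfying their assumptions — not that the biological conclusions
of any particular study are reproduced, which would require the real
384-library dataset.

## Numerical choices

* LOD is capped at 50 when $\mathrm{RSS}_1 < 10^{-12}\,\mathrm{RSS}_0$
  (noise-free fixtures would otherwise give infinities).
* Marker designs are handled by rank-aware QR; a rank-deficient marker
  contributes its column space, never an error.
* Quantile normalization resolves within-column ties by averaging the
  reference quantiles they span; the inverse-normal transform uses
  average ranks, so tied values stay tied and zero responses stay zero.
* The permutation threshold is an empirical order statistic, never an
  interpolated quantile.
* Equal-LOD plateau peaks resolve to the leftmost marker.
* All file formats are tab-separated text with a `#`-prefixed header;
  bp coordinates in annotation files are 1-based inclusive (GFF3
  convention); founder probabilities round-trip through a long-format
  table validated against the sum-to-one invariant on read.

## Problem sizes in the checks

The package's own end-to-end checks run at 96 strains on a 300-marker
10-kb grid: 500 null genes at 200 permutations for threshold
calibration (the type-I target is the 95% rule's nominal 5%), 50 planted
eQTL at 40% trait variance for detection/localization/classification,
2000 genes for the preparation-sensitive Response analysis (see the PC
caveat above), and 400 genes × 384 libraries for DE calibration and
power. These sizes were chosen so each property is measured with enough
replicates to be stable while the whole suite stays interactive.

## Known limitations

No kinship or mixed-model correction (RIL panels with equal relatedness
largely justify this, as does the original approach); no covariates
inside the scan model; no X-chromosome special-casing; no multi-QTL
joint fits or epistasis; sharing analysis is per-gene only, so cross-gene
hotspot structure is out of scope; gene sets for enrichment are
user-supplied tables, with no ontology graph propagation.
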