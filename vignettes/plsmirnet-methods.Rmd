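---
title: "Methods: PLS-based miRNA-mRNA network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLS-based miRNA-mRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsmirnet)
```

## Scope and model

`plsmirnet` infers repressive miRNA→mRNA regulations from paired
expression matrices measured on the same replicated two-condition design
(control vs. treated, typically 3 + 3 arrays). An edge must clear two
independent hurdles: sequence support (a complementary target site, or
membership in an externally supplied candidate set) and expression
support (a strong, statistically stable negative association). Neither
alone is reliable: sequence predictors over-call by an order of
magnitude, and expression association alone cannot distinguish targets
from co-responders.

The package assumes log2-scale intensities, no missing values after
loading, at least two replicates per condition, and unique feature
identifiers. miRNA action is modeled as repression, so the expected sign
of a genuine regulation is negative; positive associations are retained
in the score matrix but can be excluded from edge calling with the
repression-only flag.

## Differential expression

`moderated_t_test()` implements the standard empirical-Bayes moderated
*t*: per-feature pooled within-condition variances s²_g with d residual
degrees of freedom are shrunk towards a scaled inverse-chi-square prior
(d0, s0²) fitted by the method of moments on log s²_g (the d0 estimate
inverts the trigamma function; d0 = Inf, i.e. complete pooling, when the
observed log-variance spread is no larger than expected from chi-square
sampling alone). The statistic uses s̃²_g = (d0 s0² + d s²_g)/(d0 + d)
with d + d0 degrees of freedom. `prior_df = 0` recovers the classical
pooled-variance *t* exactly, `prior_df = Inf` a z-like fully pooled
statistic; the default estimates d0 from the data. The test suite
cross-checks the implementation against limma's reference implementation
on random matrices. Multiplicity is handled by Benjamini–Hochberg
adjustment (`bh_adjust()`, a validated wrapper around
`stats::p.adjust`); features pass at adjusted p < 0.05 by default.

Background correction is a deliberately simple floored subtraction
(max(value − background, 0.5) + 16): model-based scanner-background
estimation is instrument-specific and out of scope, and every downstream
stage consumes already-summarized matrices. Quantile normalization
(ties averaged, delegated to `limma::normalizeQuantiles`) is exposed and
optional in the pipeline; it is idempotent and leaves single-column
matrices unchanged.

## Sequence candidate filtering

`duplex_expectation()` scores a miRNA (5'→3') against a same-length
transcript window paired antiparallel. Per-position penalties — mismatch
1.0, G:U wobble 0.5, gap 2.0, all doubled within miRNA positions 2–13 —
sum to the *expectation*; 0 is perfect complementarity and sites with
expectation ≤ 2.5 are retained by `scan_transcript()` (ungapped sliding
windows, 0-based half-open coordinates, given strand only). This scheme
is a reconstruction of the expectation scoring used by plant
target-prediction servers; the published pipelines state only the tool
and the 2.5 cutoff, so all penalties are parameters. The doubled window
2–13 reflects the strong pairing constraint of the plant miRNA core,
where cleavage-site complementarity is least tolerant of lesions.

Two predictors are emulated as two candidate pair sets;
`intersect_candidates()` keeps pairs proposed by both (recording both
provenances) and `restrict_to_de()` keeps pairs whose endpoints are both
differentially expressed. A second predictor's internal parameters are
not recoverable, so it is an input, never an implementation.

## The PLS association score

For each mRNA *i* (response y_i, N samples), a PLS regression on the
full miRNA matrix X (N × p) extracts v latent components by NIPALS
deflation: w ∝ X'y (normalized), t = Xw, component coefficient
β_il = t'y/t't, followed by deflation of X by the score direction. For a
single response this is deterministic and non-iterative; scores within a
response's decomposition are mutually orthogonal (tested to 1e-8
relative).

The per-pair association aggregates the component coefficients weighted
by the loading of miRNA j on each of response i's components:

  Ŝ_ij = Σ_l β_il · p_ijl · ||t_i^(l)||² / (N − 1).

Because the scores t are X-images and mutually orthogonal, this equals
(N−1)⁻¹ · y_i' P_T x_j with P_T the orthogonal projector onto the
latent space — the sample covariance of the standardized profiles of
x_j and y_i restricted to response i's latent space, i.e. a *latent
correlation*. Its properties, all enforced by tests:

* exactly the Pearson correlation for p = 1, v = 1 (and whenever the
  latent space spans the predictor);
* bounded by 1 in magnitude (Cauchy–Schwarz), unit-free, sign-preserving
  (negative = putative repression);
* invariant to positive rescaling of any feature (autoscaling);
  negating a miRNA column negates exactly its score column.

A design note on the alternative we rejected: mapping the component
coefficients back to predictor space (B = W(P'W)⁻¹C') yields the
multivariate standardized regression coefficient. With p = 30 predictors
observed on N = 6 samples the predictors span at most a 5-dimensional
sample space, every response admits many coefficient representations,
and the PLS solution spreads weight across correlated predictors: the
per-pair coefficient is bounded in practice near 0.1–0.2 *regardless of
how strong the underlying regulation is*. A fixed edge threshold of 0.8
is meaningful only on a correlation-type scale, which the latent
correlation provides while still using the multivariate latent structure
(a miRNA scores highly only insofar as it aligns with the components
that explain the mRNA). Default v = 3 with N = 6 keeps a genuine
dimension reduction (v = N − 1 would make the score collapse to the
plain Pearson correlation).

Implementation: the user-facing `fit_pls()` stores per-response scores,
weights, loadings, coefficients and residuals. `association_scores()`
on matrices uses an algebraically equivalent fast path — the PLS1 latent
space of response i is the Krylov space span{Gy_i, G²y_i, …, G^v y_i},
G = XX' — built for all responses with a handful of matrix products and
a vectorized Gram–Schmidt (orthonormalization tolerance 1e-8 relative;
responses whose Krylov space exhausts early simply use fewer
components, matching NIPALS early stopping). The two paths are tested
for agreement; the fast path makes the 1000-fold bootstrap loops cheap.

## Significance

Each candidate pair receives a p-value from 1000 resampling iterations
(`n_boot` configurable; below 100 the 0.01 level is unstable and a
warning is raised). Two modes:

* **Paired case bootstrap (default).** Sample rows are resampled with
  replacement keeping the miRNA–mRNA pairing; p is the two-sided
  sign-crossing rate of the bootstrap score distribution with an add-one
  correction, p = min(1, 2(1 + #{sign flips})/(1 + n_boot)). This is the
  direct reading of "bootstrapping the significance of b_ij" on paired
  samples: it measures whether the association's sign is stable under
  replicate resampling, and retains resolution 2/(n_boot+1) even at
  N = 6.
* **Decoupled resampling.** Rows of X and rows of Y are independently
  resampled (`resample_null()`), destroying all X–Y dependence; p is the
  two-sided empirical tail probability of |Ŝ| with the add-one
  estimator (`empirical_p()`), never exactly 0, resolution 1/(n_boot+1).
  This null is well calibrated (the acceptance suite verifies
  super-uniformity of p under a global null by a one-sided
  Kolmogorov–Smirnov test), but at N = 6 its tail is dominated by
  chance alignment of six-point profiles — the per-pair null 99th
  percentile of |Ŝ| sits near 0.9 — so p < 0.01 is rarely attainable
  even for genuine regulations. We therefore use it as the calibration
  instrument and the paired bootstrap as the default edge-calling mode;
  the switch is one configuration flag (`sig_method`).

Degenerate bootstrap draws (a resample collapsing to one distinct row)
are redrawn deterministically from the seeded stream. FDR is
Benjamini–Hochberg over the candidate pairs only — candidate filtering
happens first, so the multiplicity burden is the candidate set, not the
full m × p grid. An edge requires |Ŝ| > 0.8, p < 0.01 and FDR < 0.05
(all three configurable; the b threshold may be disabled by setting it
to 0, and `negative_only = TRUE` additionally demands the repression
sign).

## Network analytics

`build_network()` enforces bipartiteness and set semantics.
Degree-distribution fits are ordinary least squares on the linearized
forms (log10 freq ~ log10 degree for the power law, log10 freq ~ degree
for the exponential), using raw counts with zero-frequency degrees
excluded (the intercept absorbs scale, so proportions would give the
same slope); at least three distinct degrees are required. Modules are
connected components, with at least two miRNAs, of the miRNA projection
(miRNAs linked when they share a target); each module reports the mRNAs
targeted by two or more of its miRNAs. `coregulated_fraction()` is the
share of mRNAs with in-degree ≥ 2.

The packaged network fixture transcribes the published drought-rice
edge list verbatim, preserving its internal inconsistencies (a stated
total of 69 regulations versus 67 by the per-row counts versus 66 listed
names; 58 stated versus 57 listed unique targets). All computed
quantities derive from the listed names, and the discrepancy is
surfaced rather than resolved. The fixture's degree-distribution fits
are reported as computed; the published slope/R² values are not
reproducible from the printed edge list under any obvious binning, so
they serve only as qualitative context.

## ROC validation and clustering

AUC uses the Mann–Whitney rank formulation (ties counted half), tested
against exhaustive pair enumeration and against pROC. The reported
operating point maximizes Youden's J over all midpoint cutoffs, ties
broken towards higher specificity; the classification direction is
chosen by the sign of AUC − 0.5, since downregulated miRNAs discriminate
on the low side. Hierarchical clustering defaults to centered Pearson
correlation distance (1 − r) with average linkage — uncentered
correlation, the historical default of desktop clustering tools, is
available by flag — with rows pre-sorted by id so that distance ties
break reproducibly; zero-variance features are rejected by name.
Dendrograms export to Newick via ape.

## The synthetic benchmark

`simulate_dataset()` generates the paired matrices on which every
pipeline guarantee is tested. The model, per feature on the log2 scale:

* baseline level ~ Normal(8, 1), constant across samples;
* a ± `effect_size` condition shift for DE features (default 1, i.e. a
  2-fold change, the conventional differential-expression magnitude;
  12% of DE miRNAs shifted up, matching the strong down-skew observed
  in drought studies);
* per-replicate biological variation ~ Normal(0, `bio_sd`), default 1;
* technical noise ~ Normal(0, `noise_sd`), default 0.3;
* a planted regulation (j, i) replaces mRNA i's own biological and
  condition terms by −`regulation_strength` × (x_j − mean x_j) plus
  technical noise, so the target tracks its regulator inversely and
  inherits its differential expression (default strength 0.9, 50 planted
  edges at the default 30 × 329 × 6 scale, all DE);
* the candidate set contains every planted edge plus unstructured decoys
  (each non-planted pair listed with probability `candidate_fpr`,
  default 0.02).

The biological-variation term is essential for the benchmark to be
well-posed: without replicate-level variability every strongly DE
feature is collinear with the condition contrast at N = 6, and no
expression-based method can attribute a target to one regulator rather
than another. Conversely, when condition effects dominate the
within-condition variability (as they must for DE to be detectable at
3 + 3), any correlation-scale score partially conflates direct targets
with parallel responders — this is a limitation of expression-based edge
inference itself, not of a particular score, and it is why the benchmark
defaults put the regulatory signal in the replicate-level covariation.
The generator emulates neither probe-level artifacts, nor
dye/hybridization effects, nor miRNA biogenesis, nor heterogeneous
per-feature effect sizes; passing the benchmark therefore demonstrates
the machinery's correctness and its operating characteristics under the
stated model, not performance guarantees on any particular real
dataset.

`simulate_duplex_sequences()` complements this with sequence-level
ground truth: 21-nt miRNAs and transcripts carrying planted sites that
cycle through a fixed lesion panel (perfect, one core mismatch = 2, one
non-core wobble = 0.5, one core wobble = 1, core + non-core mismatches
= 3), so the scanner can be checked against intended scores.

## Problem sizes and determinism

The test suite exercises the pipeline at the study scale (30 × 329 × 6
with 1000 bootstrap iterations, twenty seeds) for recovery — about
precision 0.88 and recall 0.63 under the default benchmark — and a
50-seed, 500-iteration global-null calibration; both complete in a few
minutes on one CPU. All randomness flows through explicit integer
seeds: identical seeds give bit-identical datasets, null distributions
and pipeline outputs (the run manifest records the seed and a config
hash so any run is reconstructible).

## Known limitations

* N = 6 is at the edge of what resampling inference supports; the
  decoupled exchangeability null is honest but low-powered there, and
  the default sign-stability bootstrap, while powerful, is a stability
  measure rather than a calibrated test — its p-values should not be
  interpreted as frequentist error rates under exchangeability.
* Condition-response confounding: two strongly condition-responsive
  features correlate regardless of direct regulation; the sequence
  gate, the b threshold and the sign constraint mitigate but cannot
  eliminate this at small N.
* The expectation scoring is an ungapped reconstruction (no bulges, no
  site accessibility/energy model, no translational-inhibition class).
* The number of latent components v is not identifiable from N = 6
  samples; it is a fixed design parameter (default 3), not estimated.
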