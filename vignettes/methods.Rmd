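---
title: "Methods: plasma NMR discrimination of lung cancer from PET-positive inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma NMR discrimination of lung cancer from PET-positive inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmetab)
```

## The problem

`18F`-FDG PET-CT flags metabolically active lung lesions, but inflammation
also accumulates tracer, so a PET-positive lesion (conventionally
SUVmax ≥ 2.5) is far from diagnostic for cancer: at a sensitivity near 96%
its specificity against inflammatory lesions is in the low twenties.
Plasma ¹H-NMR metabolomics offers a complementary, non-invasive signal.
The spectrum is segmented into 110 fixed integration regions (IRs); each
region's integral, normalized to the total integrated area (excluding the
water and TSP reference zones), is a relative metabolite concentration.
The region covering 2.197–2.218 ppm (IR89, the downfield part of the
glutamate β-CH₂ multiplet, possibly with a methionine contribution) is
markedly elevated in inflammation relative to cancer, which makes a *low*
relative glutamate level evidence for cancer.

`lungmetab` implements the full analysis around that idea: a PLS-LDA
classifier over the 110-region fingerprint with nested LASSO top-K feature
selection, a balanced repeated cross-validation engine, univariate
screening, ROC/cutoff analysis of the glutamate region, and a combined
SUVmax/glutamate decision rule — together with a synthetic cohort
generator so every stage is testable without patient-level data (the
underlying monocentric trial data are not deposited anywhere public).

## The classifier

The estimator fitted by `plslda()` is a three-stage pipeline, always
trained on the training partition only:

1. **Autoscaling.** Each feature is centered and scaled to unit SD using
   training means/SDs. Zero-variance features are an error, not silently
   dropped.
2. **LASSO top-K selection.** An L1-penalized least-squares path is fit to
   the ±1-coded class label (`glmnet`), and features are ranked by the
   order in which they first enter the active set as the penalty
   decreases. The first K features form the signature. This realizes
   "top K" without committing to one penalty value; for orthonormal
   designs it provably reduces to ranking by |xᵀy|, which is the oracle
   used in the tests. Exact duplicate columns enter together; the smaller
   index wins. The least-squares (rather than logistic) path keeps the
   selection consistent with the PLS regression framing and admits the
   closed-form oracle.
3. **PLS + LDA.** NIPALS PLS with A latent components is fit to the
   ±1-coded response on the selected features; a linear discriminant with
   equal class priors is fit on the A-dimensional score matrix. Scores of
   new subjects are `X R` with `R = W (PᵀW)⁻¹`. A subject exactly on the
   boundary goes to the first class level in sort order — an explicit
   tie rule rather than an accident of floating point.

**Latent components.** The component count is not prescribed by the
original analysis, so the default `ncomp = "auto"` picks A ∈ 1..min(8, K)
by an internal, deterministic stratified four-fold error estimate on the
training set (folds dealt round-robin within class, no RNG consumed, so a
fitted model is a pure function of its inputs). A fixed A can be supplied
for speed or strict reproducibility of older runs; the per-stage LOOCV
defaults to A = 2 because it refits the pipeline once per subject.

## Cross-validation design

The cohort is imbalanced (269 cancer vs 108 inflammation), and classifiers
trained on it drift toward the majority class. `balanced_repeated_cv()`
therefore repeats, 250 times by default:

- draw a random majority-class subsample of minority size (108 vs 108);
- deal a stratified four-fold partition, keeping the 1:1 balance per fold;
- in each fold, run the *entire* nested pipeline (scaling, selection, PLS,
  LDA) on the 3/4 training portion and score the held-out 1/4.

That yields 250 × 4 = 1000 fold evaluations; misclassification error,
sensitivity and specificity are averaged over evaluations, and each
feature's selection frequency is the fraction of evaluations whose top-K
set contained it. One master seed derives all per-repeat seeds, so a run
is exactly reproducible. On balanced folds MCE ≈ 1 − (sens + spec)/2 up to
integer fold sizes; the suite asserts this identity.

`ablation_cv()` deletes named columns and reruns the identical schedule —
same master seed, same subsamples and folds — so ablated and full runs are
paired. `loocv_per_stage()` balances once, then leaves each subject out in
turn with full nested refitting, attributing each held-out cancer
subject's error to its TNM stage; stages with no subjects report `NA`
("not applicable"), never a fake 0. Stratification of folds is our choice
(the source analysis does not state it); it removes fold-composition noise
without touching the train/test contract.

## The synthetic cohort generator

`generate_cohort()` emulates the published cohort structure: 269 cancer /
108 inflammation / 347 control subjects; the published TNM stage counts
(IA 53, IB 22, IIA 16, IIB 16, IIIA 63, IIIB 28, IV 71) assigned
deterministically rather than multinomially, so stage margins match
exactly; SUVmax 12.1 ± 7.6 (cancer) and 4.3 ± 2.8 (inflammation), absent
for controls; relative glutamate 0.159 ± 0.156 / 0.485 ± 0.237 /
0.152 ± 0.113; and secondary discriminating regions (defaults in IR15 and
IR96, the tyrosine and alanine/isoleucine/lysine regions) with
configurable separations.

**Positive-support sampling.** Only means and SDs are published, and the
cancer group's coefficient of variation is ≈ 0.98, so a normal model would
put substantial mass below zero. `rpositive()` draws from a gamma with
shape (μ/σ)² and scale σ²/μ — non-negative support, first two moments
matched exactly.

**Exact relative concentrations.** Effect regions are sampled on the
relative-concentration scale; background regions (i.i.d. gamma, identical
across groups) are rescaled within each subject to fill the remaining
mass; the whole vector is multiplied by a per-subject total area
(gamma, mean 100, CV 0.2) to produce raw integrals. Normalization by
`normalize_total_area()` then recovers the sampled relative values to
machine precision, so the marker distributions downstream are exactly the
configured ones (up to the truncation below).

**Compositional truncation.** Relative concentrations sum to 1, and the
published inflammation moments imply a gamma with ≈ 3.3% of its mass above
1 — impossible for compositional data. Draws whose summed effect values
reach 0.999 are rejection-resampled, so the realized inflammation
glutamate mean is ≈ 0.46 rather than 0.485 (about one within-group SD/√n
at n = 108); cancer and control truncation mass is below 0.3% and
negligible. This is an intrinsic tension between the printed unbounded
moments and the simplex, not a tunable artifact.

**Compositional closure.** A second consequence of normalization: when one
region occupies a large, class-dependent share of the total area, every
*other* region inherits the complementary (1 − share) factor and becomes
informative about class. At the printed glutamate shares this closure
leakage is strong — removing IR89 from a default synthetic cohort does not
cripple the classifier the way the published 12% → 38% MCE jump suggests,
because the background regions collectively encode 1 − glutamate. The
feature-selection and ablation properties are therefore tested on
one-signal cohorts whose marker share sits at the background scale
(≈ 1–2% of total area), where closure is negligible and "only the
configured effect carries signal" holds by construction. This is a real
limitation of emulating the study from printed group moments alone: the
real spectra evidently distribute variance across many regions in a way
group-level summaries cannot reconstruct.

**SUVmax dependence.** By default SUVmax is conditionally independent of
the glutamate level given class; a Gaussian-copula rank correlation knob
(`suvmax_glutamate_rho`) is available because the joint distribution was
never published, only the marginals and the combined-rule outcomes.

## Univariate screen and volcano classes

`univariate_screen()` runs a Welch t-test per region with
Benjamini–Hochberg correction applied jointly across all 110 tests. The
Welch (unequal-variance) form is used because the published group SDs of
the discriminating regions differ by more than two-fold. Fold change is
mean(group_b)/mean(group_a) with the (cancer, inflammation) ordering, so
values above 1 are elevated in inflammation. `volcano_table()` labels each
region `significant` (adjusted p < 0.05), `high_fc` (non-significant but
|log2 FC| ≥ 1) or `negligible`; both thresholds are arguments, since the
original figure shows the classes without printing its cutoffs.

## ROC, cutoff and the combined rule

`roc_curve()` sweeps thresholds at the midpoints between consecutive
distinct marker values plus the observed values themselves and ±∞
sentinels; with direction `"lower"`, a subject is called positive when
value ≤ threshold (the glutamate convention). `auc_empirical()` is the
trapezoidal area and equals the tie-corrected Mann–Whitney probability
exactly — the suite asserts the identity on random instances.
`auc_binormal()` is the two-normal closed form Φ(Δμ/√(σ₁² + σ₂²)); with
the published group moments it reproduces the published AUC of 0.875, and
that agreement is one of the package's acceptance checks.
`youden_cutoff()` maximizes J = sens + spec − 1, ties broken toward the
smaller threshold (the original analysis reports a single cutoff, 0.31,
without discussing ties).

`metrics_from_rates()` keeps fractional expected 2×2 cells (no integer
rounding), which makes the derived PPV/NPV reproducible and
order-independent; recomputing the published predictive values from the
published sensitivities/specificities at the 269/108 prevalence matches to
the nearest percent for PPV and within 1–2 points for NPV (the original
table presumably rounded through integer counts).

`combined_rule()` applies both cutoffs with the published inclusive
boundaries (SUVmax ≥ 2.5 is PET-positive, glutamate ≤ 0.31 is
cancer-suggestive) and yields four categories; `stratified_metrics()`
tallies correctness per category. In discordant categories the final call
follows the glutamate test by default — that choice makes the "missed
cancer" fraction meaningful (a discordant PET-positive cancer with high
glutamate is missed); following PET instead, or forcing either call, are
options. The published headline rates for the combined rule (100%
sensitivity, 94% PPV, 100% NPV, 19% missed) depend on the unpublished
joint SUVmax–glutamate distribution and are deliberately not acceptance
targets; with the default conditional-independence generator the
discordance pattern differs from the real cohort's.

## Problem sizes and numerical choices

The test suite runs the full 250 × 4 engine once on a full-size
(269 vs 108) cohort at K = 16; all other CV properties use downscaled
cohorts (around 40 vs 24 subjects, 30 regions, 5–20 repeats), which keeps
the whole suite around a minute while still exercising every code path.
Further choices worth stating: region membership is half-open
[ppm_low, ppm_high) so shared boundaries are unambiguous; integration is
trapezoidal (the quadrature rule was never stated); only IR15, IR72, IR89
and IR96 have published ppm bounds and annotations, the remaining 104
regions carry placeholder bounds partitioning 0.3–4.7 and 5.2–10 ppm
(downstream statistics use only indices, never bounds); the all-zero
integral vector is a normalization error, never a silent NaN; and cohort
CSVs are written with 17 significant digits so round trips are exact.

## What passing tests do and do not show

The suite establishes that the machinery is correct: selection order
matches the orthonormal-design closed form, PLS at full rank equals least
squares, PLS-LDA at full rank equals a direct equal-prior LDA, empirical
AUC equals the Mann–Whitney oracle, the CV engine never leaks test rows
into training, permuted labels give chance error, and the generator
reproduces its configured structure and moments. What it cannot show is
fidelity to the real cohort beyond the printed group statistics: the
published real-data MCE (12%), its ablated value (38%), the CV
sensitivities/specificities and the combined-rule rates all depend on
per-subject data that were never released, and the synthetic cohorts make
distributional choices (gamma margins, independent backgrounds,
class-conditional independence of the markers) that real plasma spectra
will violate in unknown ways.
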