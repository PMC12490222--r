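---
title: "Methods: image-based ex vivo drug sensitivity profiling for pediatric AML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based ex vivo drug sensitivity profiling for pediatric AML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`blastscreen` implements the analytical machinery of image-based ex vivo
drug sensitivity profiling in pediatric acute myeloid leukemia (pedAML):
per-cell feature tables from a high-content screen of primary mononuclear
cells are turned into quality-controlled well summaries, blast-specific
dose-response scores, drug and drug-class correlation structure,
chromatin-accessibility cell-state projections, and cross-validated
predictions of clinical response. Because primary patient screens are not
desk-available, the package ships a first-class synthetic cohort
generator whose defaults encode the assay geometry the analysis assumes;
every downstream stage is tested by parameter recovery against the
generator's planted truth.

The pipeline runs in R; `run_pipeline()` orchestrates the stages into a
run directory with a manifest, and the exported stage functions are the
programmatic interface.

# Assay geometry and the synthetic cohort

Each sample is screened on two 384-well plates carrying 115 compounds at
3 concentrations in technical duplicate plus 32 DMSO solvent-control
wells per plate, seeded at 9,000 cells per well. The generator
reproduces exactly this geometry (`generate_plate_layout()`, seeded
randomized positions on a 16 x 24 row-major grid, ids "A01".."P24").
The screening concentrations are an assay-specific choice, so the
generator declares a per-compound 3-point geometric grid (0.1, 1, 10 uM)
as configuration rather than reproduction.

`simulate_cohort_truth()` draws, per sample:

* a probability vector over eight healthy hematopoietic cell states
  (HSC, MPP, lpMPP, CMP, GMP, MEP, monocyte, erythroblast) from a
  GMP-dominated Dirichlet prior; 40% of samples are pushed toward a
  differentiation extreme (monocyte-like or HSC-like) by boosting the
  corresponding concentration, mirroring the bimodal deviation of
  poor-response samples from the cohort's average phenotype;
* per-compound Hill-curve potencies (maximal kill in [0,1], EC50, slope)
  on the logit/log scale around class-level baselines, with planted
  couplings: a shared apoptotic-priming factor loads positively on HDAC
  inhibitors, proteasome inhibitors and venetoclax (combinations), and
  negatively on FLT3 inhibitors; the sample's HSC probability raises
  venetoclax-class maximal kill; a latent chemosensitivity factor drives
  chemotherapy response and is depressed for samples at either
  differentiation extreme (primitive and monocytic states are
  chemoresistant);
* clinical labels: the log10 measurable-residual-disease (MRD) burden is
  a linear function of standardized mean chemotherapy kill (negative
  coefficient) and the extreme indicator plus Gaussian noise; status is
  positive at 0.1% blasts and the prediction endpoint uses the 1% cut.
  13 of 45 samples have undetermined MRD, leaving 32 evaluable. Risk
  (SR/IR/HR) is a noisy quantile cut of the same latent axis; relapse
  times are drawn with a hazard increasing in the risk score and censored
  at the follow-up time.

Setting every effect size to zero provably decouples states from
potencies; type-I-error calibration of the downstream tests relies on
this switch. Effect sizes the assay protocol does not pin down
(priming loading 1.3, FLT3 loading -1.6, HSC-venetoclax 3 on the logit
scale, MRD coefficients -2.2/2.0, potency spread 0.8, EC50 jitter 0.25
on the natural-log scale) were fixed once by large-n simulation so the
planted structure is comfortably detectable at cohort size n = 45, and
are recorded in `cohort_config()`.

Cell-level tables (`simulate_cell_table()`) draw Poisson well totals at
the seeding density times a 0.7 plating efficiency, multinomial class
composition (60% blasts, 15% T cells), binomial survival under the
sample's Hill curve (off-target kill applies to non-blast cells with the
same curve shape; killed cells remain in the well as nonviable objects,
so total counts are treatment-independent), class-conditional Gaussian
morphology features, and lognormal dye/marker intensities whose
viable/nonviable modes sit 10 component-SDs apart on the log scale by
default. A full 45-sample cohort at 9,000 cells/well would materialise
~10^8 cells, so `simulate_well_summaries()` draws the identical
well-level law directly (cells are exchangeable given the per-well
counts); cell-level tables are used wherever the annotation stage itself
is under test.

Accessibility matrices (`simulate_region_matrix()`) give each cell type
80 signature regions (of 2,000) elevated 4-fold over a lognormal
baseline, negative-binomial counts (size 20), six labeled reference
samples per type, and cohort profiles that are state-probability-weighted
mixtures of the type means. What the generator does *not* emulate:
plate-edge and inter-plate batch effects, staining chemistry, correlated
morphology-viability structure beyond the class conditionals, overlapping
real chromatin signatures, or library-specific GC/peak-width biases.
Passing recovery tests therefore demonstrate the correctness of the
analytical machinery under the stated statistical assumptions, not
performance on real screens.

# Cell annotation

**Well QC** excludes wells whose mean intensity in any imaged channel is
at least 4 SDs away (two-sided) from the grand mean of well means;
channels with zero spread never exclude. **Cell QC** thresholds
morphology descriptors on declared intervals.

**Viability labeling** follows a five-stage semi-supervised procedure:
reduce morphology features (PCA to 2 components by default; UMAP via
`uwot` available behind `reduce = "umap"`), cluster in the reduced space,
fit a two-component unequal-variance Gaussian mixture to log10 dye
intensities within each cluster, keep only confident assignments, and
veto labels whose k-nearest-neighbour vote disagrees. Design choices the
procedure leaves open, decided here:

* Clustering is Gaussian-mixture model-based (mclust, BIC over 1-6
  components, fit on a seeded 5,000-cell subsample and extended to all
  cells); clusters below `min_cluster_size` (200) are treated as density
  noise and never labeled. The per-cluster dye mixture additionally
  tries a midpoint-split EM start, which rescues strongly unbalanced
  mixtures that hierarchical initialization misses; the
  highest-likelihood valid fit wins and fits with collapsing components
  fall back to a shared variance.
* Dye polarity: the higher-mean component is nonviable (fixable
  viability dyes stain membrane-compromised cells); configurable.
* The "3 SD" confidence rule is read as two cuts: a cell must lie at
  least `sd_away` (3) component SDs from the opposite component *and*
  within `sd_within` (3) SDs of its own. Splitting the two cuts keeps
  the headline cut monotone - raising `sd_away` can only remove labels -
  while `sd_within = Inf` recovers the pure "away" reading.
* The KNN consensus (k = 15) runs in the reduced space joined with the
  scaled log dye intensity. The KNN model is trained on the raw mixture
  assignments of all clustered cells (against a seeded reference
  subsample of 5,000 for speed), not on the confidence-filtered subset,
  so the consensus is independent of the confidence cut.

**Cell typing** is a pluggable contract; the default implementation gates
marker intensities (auto gates at the equal-density boundary of a
two-component mixture on log10 intensity): T if any T-marker exceeds its
gate, blast if a blast-marker exceeds its gate and no T-marker does,
other otherwise. The trained image classifier of a production pipeline
can be swapped in behind the same interface.

**Well summaries** count viable cells by class; unlabeled cells are
excluded from both numerator and denominator by default. Wells without
viable cells are flagged and never scored.

# Dose-response scoring

For each sample, treated wells whose total cell count exceeds the DMSO
mean by more than 4 control SDs (high side only) are removed. The
relative blast fraction (RBF) divides each treated well's viable blast
fraction by the control mean; values above 1 (resistance) are not
capped. Two outlier rules then filter each compound's series: (A) in
ascending concentration order, any replicate more than 50% above the
running filtered average of the previous retained concentration is
dropped; (B) concentrations whose two replicates differ by more than 50%
of their mean are dropped (single replicates are exempt). The pair of
rules is iterated to a fixpoint so the filter is exactly idempotent; the
replicate-difference denominator is the replicate mean, and rule A's
baseline is the already-filtered average (both left open by the verbal
rule; recorded as switches).

The inhibition score integrates the per-concentration mean values with
the trapezoid rule over equally spaced concentration indices mapped to
[0, 1] and reports `1 - AUC`: 0 for an untreated-like flat series at 1,
1 for complete kill, negative for resistance. A log-molar axis is
available behind `axis = "log10"`. Applied to RBF values this is the
RBF-AUC; applied to control-normalized absolute viable-blast counts it is
the Blast AUC (total activity, ignoring blast specificity). Linear
interpolation onto a common grid (`interpolate_series()`, log10 axis,
no extrapolation) supports heterogeneous concentration ranges. Cohort
matrices are z-scaled per compound with the population-SD convention
(divide by n), matching the scientific-Python stack's default; constant
columns scale to 0 and are flagged.

Three-parameter curve fits (`fit_dose_response_3p()`) hold the top at 1
and fit bottom, log EC50 and slope by Levenberg-Marquardt least squares
from the deterministic start (min value, median log concentration, slope
1), with bounds wide enough for resistant series; flat series are
flagged degenerate.

# Correlation analysis

Compounds with a Blast AUC of at least 0.25 in at least 3 samples are
"active" (inclusive counting; missing entries never qualify). Pairwise
Spearman correlations use pairwise-complete observations and average
ranks; two-sided p-values come from the exact full permutation
distribution below n = 10 complete tie-free pairs (the null distribution
per n is enumerated once and cached) and from the t-approximation
otherwise. Benjamini-Hochberg adjustment is applied once across all
unique pairs of a score kind (one family per score kind). A class pair
is "consistent" when every cross-class drug-pair coefficient shares one
strict sign - a zero or missing coefficient breaks consistency -
reported with the mean coefficient and the fraction of pairs with
adjusted p < 0.05; within-class pairs are excluded by default.

# Cell-state projection and the Mono-HSC propensity score

Counts are log2-CPM(+1) normalized (the heavier conditional-quantile and
batch-correction chain of a full ATAC workflow is out of scope here; the
generator produces data compatible with this transform). The classifier
is an RBF-kernel SVM with balanced class weights on the 1,000 most
variable reference regions (reference-only variance, ties broken by
region id). Probabilities come from one-vs-rest decision values passed
through 3-fold cross-validated Platt sigmoid calibration (smoothed
targets keep separable folds finite) and normalized to sum to one; this
keeps the whole fit deterministic under a fixed seed, which libsvm's
internal probability machinery does not guarantee.

The Mono-HSC propensity score quantifies deviation from the cohort's
average phenotype toward either differentiation extreme:

```
score_s = max( P_mono,s / max_t P_mono,t , P_HSC,s / max_t P_HSC,t )
```

with maxima over the cohort passed in (the caller decides the cohort
subset). Scores lie in (0, 1] and are invariant to rescaling either
probability column. Group associations use the Mann-Whitney U test:
exact when both groups have at most 8 tie-free observations, normal
approximation with tie and continuity correction otherwise; the reported
U is the first group's rank sum minus n1(n1+1)/2.

# Clinical prediction

Binary endpoints: MRD at the 1% cut (undetermined samples excluded),
non-standard risk (IR or HR, i.e. not SR - the reading under which all
45 samples are evaluable), and early relapse (within 365 days; samples
with neither a relapse nor 365 days of follow-up are excluded).
Prediction uses a random forest of 101 trees, each grown on the full
training set without bootstrap resampling, with class weights inversely
proportional to class frequency (ranger, single-threaded for
determinism), evaluated by seeded stratified 5-fold cross-validation on
unscaled RBF-AUC features (forests are scale-invariant). Feature
importances (impurity, normalized to sum 1) from a forest on all
evaluable samples are reported against the per-compound difference in
mean z-scaled inhibition between label groups.

# Numerical choices and degenerate inputs

* One integer master seed fans out to named per-stage streams
  (`stream_seed()`), so any stage can be regenerated independently and
  the demo pipeline is byte-reproducible.
* Wells with zero viable cells, series emptied by filtering, compounds
  with fewer than 2 retained concentrations, and constant columns are
  flagged (with reasons) rather than scored.
* Zero-SD QC channels exclude nothing; the cell-count filter with
  zero-SD controls removes only wells strictly above the common count.
* Spearman coefficients of exactly +/-1 under the t-route return p = 0;
  the exact route handles them by enumeration.
* Mixture fits that collapse (vanishing component SD) are discarded; the
  affected cluster simply stays unlabeled.

# Problem sizes used by the test suite

The acceptance checks run the full cohort geometry (45 x 115, two
384-well plates) for potency recovery and class-coupling recovery (20
seeds), the labeling check on a ~59,000-cell single-sample table, the
propensity power analysis on 50 full-size cohorts with the null size
calibrated on 220 reduced cohorts (n = 16, 300 regions, 3 reference
samples per type), and the demo pipeline (12 samples x 20 compounds at
reduced seeding density) twice for byte-identity. These sizes are the
package's declared test conditions; the generator scales to larger
cohorts by configuration.

# Known limitations

The generator's independence assumptions (features conditionally
independent given class and viability; shared concentration grid; no
batch structure) make the labeling and classification tasks cleaner than
real screens - the ~30% labeling rates typical of production screens
arise from population overlap that the default configuration does not
produce. The default gating
classifier is a stand-in contract for a learned cell-type model. The
cell-state projection replaces a full ATAC normalization chain with
log2-CPM. Clinical accuracies published for patient cohorts are not
reproduction targets: they depend on patient data this package does not
ship.
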