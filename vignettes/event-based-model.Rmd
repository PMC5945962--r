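---
title: "Event-based modelling of regional brain-volume progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based modelling of regional brain-volume progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

Huntington's disease progresses through a cascade of regional brain-volume
changes. The event-based model (EBM) formalises this as an ordered sequence
of *events*, each event being the transition of one biomarker $i$ from its
normal distribution $P(x \mid \neg E_i)$ to its abnormal distribution
$P(x \mid E_i)$. Two strong assumptions underpin it: progression is
*monotonic* (no remission) and *homogeneous* (every subject follows the
same ordering). A subject at stage $k$ has experienced exactly the first
$k$ events of the sequence $S$, so the likelihood of a dataset
$X = \{x_{ij}\}$ of $Z$ biomarkers in $N$ subjects under an ordering $S$ is

$$
P(X \mid S) \;=\; \prod_{j=1}^{N} \sum_{k=0}^{Z} P(k)
  \prod_{i=1}^{k} P\!\left(x_{s(i)j} \mid E_{s(i)}\right)
  \prod_{i=k+1}^{Z} P\!\left(x_{s(i)j} \mid \neg E_{s(i)}\right),
$$

with a uniform stage prior $P(k) = 1/(Z+1)$ so that no stage is favoured a
priori. The *characteristic sequence* $\bar S$ maximises this likelihood.
Staging is the single-subject analogue: given $\bar S$, subject $j$ is
assigned the stage $k$ maximising
$P(k)\prod_{i \le k} P(x_{ij}\mid E_i)\prod_{i > k} P(x_{ij}\mid\neg E_i)$,
so a stage is a count of events undergone, from 0 (none) to $Z$ (all). The
model needs only cross-sectional data and imposes no a priori cut points —
both properties that matter for stratifying premanifest gene carriers.

## From raw volumes to event distributions

**Covariate correction.** Regional volumes scale with head size and drift
with age and acquisition site, so each biomarker is first regressed on age,
total intracranial volume and site (OLS, reference-level dummy coding for
site) and replaced by its residuals. The regression is fitted on healthy
controls only and then applied to everyone: control residuals are anchored
at mean zero, and disease atrophy cannot leak into the covariate
coefficients. Fitting on the pooled sample is available via
`fitGroup = "all"`; the choice matters when the patient fraction is large
and atrophy correlates with age. Constant covariates are dropped from the
design automatically, so a single-site cohort reduces gracefully.

**Selection.** Biomarkers enter the model only if they separate controls
from manifest patients: a two-tailed Welch $t$-test per biomarker with
Bonferroni-corrected $p < 0.001$ and $|t| > 8$. Welch rather than pooled
variance because the fitted abnormal components routinely have SDs unlike
the control SDs; Bonferroni because the correction method is then
order-preserving in $|t|$, keeping the two thresholds consistent. Bilateral
(left/right) volumes are retained only when both sides pass — a deliberate
guard against including one-sided, possibly artefactual effects. Including
biomarkers that do not separate the groups is worse than excluding
informative ones: an uninformative biomarker adds a near-flat likelihood
channel whose position in the sequence is then decided by noise.

**Outlier removal.** Any subject with a corrected value more than 5
within-diagnosis-group SDs from the group mean is removed entirely (the
failure mode is a bad segmentation affecting one scan, i.e. one subject,
rather than one cell). Removal is logged per subject and biomarker.

**Event distributions.** $P(x\mid\neg E_i)$ is a Gaussian fitted to the
control values by maximum likelihood (divisor $n$; at control group sizes
above 100 the distinction from the unbiased estimator is immaterial, but it
is the documented convention). $P(x\mid E_i)$ comes from a two-component
Gaussian mixture fitted to the *manifest patients only*, with the normal
component frozen at the control fit and the abnormal mean, SD and mixing
weight estimated by EM. Premanifest subjects are excluded from fitting —
their event status is unknown — but included when the sequence likelihood
is evaluated, where they are the most informative subjects for ordering
mid-sequence events. EM details: initialisation at the patient sample mean
and SD with weight 0.5; tolerance $10^{-6}$ on the log-likelihood; at most
500 iterations (non-convergence returns the current fit with a warning,
which in practice occurs for biomarkers whose abnormal fraction in the
patient group is very small); the abnormal SD is floored at 0.05 control
SDs to prevent density spikes — small on purpose, since genuinely narrow
abnormal components do occur; the weight is clamped to $[0.01, 0.99]$ so
both likelihood channels stay defined. The fitter does not constrain the
direction of the abnormal shift: fluid spaces (CSF, third ventricle) grow
while grey-matter volumes shrink, and both signs must be representable.

## Sequence inference

All likelihood arithmetic is in log space: per subject, the $Z+1$ stage
terms are prefix/suffix sums along the candidate ordering combined by
log-sum-exp, an $O(NZ)$ evaluation implemented in C++ because the search
and the MCMC chain evaluate it on the order of $10^5$ times. The literal
product form of the likelihood underflows already at a few hundred
subjects; the test suite keeps a deliberately naive product-form evaluator
as an independent oracle at toy sizes.

The search strategy is greedy hill-climbing over pairwise swaps from
random restarts (10 by default), followed by Metropolis–Hastings sampling
over permutations with symmetric random-swap proposals; the characteristic
sequence is the highest-likelihood state visited by either phase. The MCMC
refinement is not cosmetic: pairwise-swap ascent alone can stall in local
optima whose likelihood is visibly below the planted ordering's even on
cleanly generated data, and the chain escapes these reliably. On
*unstructured* (pure-noise) likelihood tables the landscape is more rugged
still; the oracle-equivalence tests therefore give the greedy a larger
restart budget (40), which was sufficient for every one of 200 random
tables at $Z \le 6$ in calibration runs. Exhaustive enumeration
(`exhaustiveMLSequence()`) is available up to $Z = 8$ and is the oracle the
search is tested against; ties there resolve to the lexicographically
smallest permutation (within a $10^{-10}$ relative tolerance, since
permuting the order of a sum reorders floating-point additions).

Positional uncertainty is reported as a positional variance diagram (PVD):
entry $(i, p)$ is the posterior frequency with which biomarker $i$ occupies
position $p$, rows displayed in characteristic-sequence order. Every MCMC
sample contributes exactly one position per biomarker, so rows and columns
each sum to one — an invariant the classes enforce. MCMC-based PVDs
understate uncertainty, so `bootstrapPVD()` re-estimates everything
(mixtures and sequence) on resamples drawn with replacement, stratified by
diagnosis so each resample contains both fitting groups, and averages the
per-resample PVDs. The per-resample PVD is the permutation matrix of that
resample's maximum-likelihood sequence: out-of-sample variability is then
expressed purely as disagreement *between* resamples, which keeps the
noise-free limit exact (identical resample optima average to a permutation
matrix). Per-resample chains can be enabled via `nMCMC` when a blend of
within- and between-resample uncertainty is wanted.

## Staging and validation

Stage ties resolve to the smallest $k$ — a subject is never staged later
than the evidence requires. Validation analyses mirror the intended use of
the staging system:

- `longitudinalConsistency()` — under monotonic progression, follow-up
  stages should not regress; the report gives the fraction of subjects
  whose final stage is at least their baseline stage, and mean
  progression/regression among movers. Follow-up visits are staged with
  the baseline-fitted mixtures and sequence; refitting per visit would
  conflate model change with subject change.
- `predictConversion()` — premanifest subjects above a baseline stage
  threshold are predicted to convert to manifest disease; the threshold is
  chosen to maximise balanced accuracy (mean of sensitivity and
  specificity), sweeping every threshold $t \in \{0..Z\}$ and taking the
  smallest maximiser.
- `phenotypeRegression()` — OLS of each clinical score on assigned stage
  over the combined patient cohort; motor impairment (TMS) and genetic
  burden (CAP) should increase with stage, cognitive scores (SDMT, Stroop)
  decrease.
- `stageDistribution()` — per-group stage occupancies, with a lower/upper
  half split at $\lfloor Z/2 \rfloor$ (configurable) for coarse
  stratification summaries.

## The synthetic cohort generator

No individual-level clinical data ship with the package, so every analysis
is exercised on synthetic cohorts that reproduce the statistical structure
the model assumes, with defaults chosen to mirror the study design the
package targets: three diagnostic groups of 119/120/118 subjects from four
acquisition sites, $Z = 18$ events, group-specific age and TIV
distributions, abnormal shifts of about 3 control SDs (signed per
biomarker), and linear age/TIV/site confounding that the preparation step
must remove. Stage occupancy defaults to a geometric decay from stage 0
for controls (most controls have experienced no events) and a uniform
distribution over all stages for gene carriers — a qualitative mimic of
the observed occupancy shapes, which are not published numerically, and
deliberately simple. Follow-up visits advance true stages by capped
Poisson increments (expectation `stagesPerYear` per year, 1 by default,
matching the roughly one-stage-per-year progression the staging system
recovers), redraw biomarker values at the visit's stage, and flag
premanifest subjects whose true stage reaches 13 — the stage bracket
associated with motor onset — within 36 months as converters. Phenotype
scores are linear in true stage (default slopes +0.98 for TMS, −1.0 SDMT,
−1.4 Stroop, +0.014 CAP) with Gaussian noise.

Each generator operation draws from its own seed stream derived from the
config seed, so adding phenotypes or visits never perturbs the biomarker
draws, and identical configs reproduce identical tables bitwise.

What the generator does *not* emulate: segmentation error structure,
correlated residuals between neighbouring regions (the model itself
assumes biomarker independence), heterogeneous orderings or disease
subtypes, non-linear phenotype trajectories, and CAG-repeat genetics.
Passing tests on synthetic data therefore demonstrate correctness of the
machinery under the model's own assumptions, not robustness to their
violation on real scans.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at deliberately chosen sizes:
sequence-recovery checks use the full study scale (357 subjects, 18
events, ten replicate seeds) with 20,000-sample refinement chains, which
recovers planted orderings at Kendall's $\tau \ge 0.9$ in at least 9 of 10
seeds; staging accuracy uses 1,000 subjects; mixture recovery uses the
study's manifest group size (118) over 20 seeds; oracle-equivalence checks
use $Z \le 6$ where enumeration is exact. Longer chains (the
100,000-iteration default of `estimateSequence()`) sharpen PVDs but do not
change the recovered sequences at these separations.

Other conventions, fixed and documented rather than silently defaulted:
stages are reported 0-based (stage 0 = no events) and sequence positions
1-based (position 1 = earliest event); the equal-likelihood abnormality
threshold solves the component-density crossing and takes the root between
the component means, falling back to the root nearest their midpoint; the
threshold is descriptive output only and is never used by the model.

## Limitations

The homogeneity assumption is the model's strongest: a single ordering is
fitted to the whole cohort, and systematic subtype structure would be
averaged away rather than detected. The independence assumption means
strongly co-atrophying regions contribute overlapping rather than
complementary evidence. The model has no intrinsic time scale — stages are
ordinal, and the phenotype regressions provide only an implicit
calibration. Missing biomarker values are rejected rather than imputed,
and staging requires the complete biomarker vector used to fit the model.
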