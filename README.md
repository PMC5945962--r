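# ebmHD

Event-based modelling of regional brain-volume progression in Huntington's
disease.

## The problem

Huntington's disease is monogenic, so gene carriers can be identified
decades before motor onset — but trials in the premanifest period need a
way to stage participants. `ebmHD` implements the event-based model (EBM),
which infers, directly from *cross-sectional* data, the order in which
regional brain-volume biomarkers become abnormal, and then assigns each
subject a stage: the number of events they have undergone. No a priori
staging, no imposed abnormality cut points.

An *event* is the transition of biomarker *i* from its normal distribution
P(x|¬Eᵢ) to its abnormal distribution P(x|Eᵢ). With Z biomarkers, N
subjects and an ordering S, the dataset likelihood is

    P(X|S) = ∏ⱼ ∑ₖ P(k) ∏_{i≤k} P(x_{s(i)j}|E_{s(i)}) ∏_{i>k} P(x_{s(i)j}|¬E_{s(i)})

with a uniform stage prior P(k) = 1/(Z+1). The characteristic sequence S̄
maximises this; a subject's stage is the k maximising the inner product
for their own data under S̄. Normal components are Gaussians fitted to
healthy controls; abnormal components come from patient mixtures with the
control component held fixed. Sequence uncertainty is summarised as
positional variance diagrams from MCMC over permutations and from
bootstrap re-estimation.

The package covers the full workflow: covariate correction (age, total
intracranial volume, site), data-driven biomarker selection (Welch t-test,
Bonferroni p < 0.001 and |t| > 8, with a bilateral left/right rule),
5-sigma outlier removal, constrained mixture fitting, greedy + MCMC
sequence inference, staging, and the validation analyses (bootstrap
cross-validation, longitudinal consistency, conversion prediction,
phenotype regression). A synthetic cohort generator with a planted event
ordering makes everything testable without clinical data.

## Worked example

Simulate a study-sized cohort (119 controls / 120 premanifest / 118
manifest, four sites) with eight regional events and run the pipeline:

```r
library(ebmHD)

regions <- c("putamen", "caudate", "pallidum", "insula_wm", "csf",
             "amygdala", "optic_chiasm", "third_ventricle")
Z <- 8L
hdOcc <- 0.65^(Z:0); hdOcc <- hdOcc / sum(hdOcc)   # manifest: late stages
hcOcc <- 0.35^(0:Z); hcOcc <- hcOcc / sum(hcOcc)   # controls: early stages
cfg <- cohortConfig(
  nBiomarkers = Z, biomarkerNames = regions,
  abnormalShift = c(-4, -3.8, -3.6, -3.5, 3.4, -3.3, -3.2, 3.2),
  stageOccupancy = list(HC = hcOcc, preHD = rep(1/(Z+1), Z+1), HD = hdOcc),
  seed = 2026)
cohort <- generatePhenotypes(generateCohort(cfg))
res <- runEBMPipeline(cohort, nMCMC = 5000, nBurnIn = 500, seed = 2026)
```

Selection keeps seven of the eight planted events and drops the last
(`third_ventricle`, |t| = 5.0 < 8 — the latest event is abnormal in the
fewest patients, so it is the hardest to power):

```
        biomarker          t        p_adj selected
1         putamen -11.191986 1.032336e-21     TRUE
2         caudate -19.292789 1.376299e-48     TRUE
...
8 third_ventricle   4.968434 1.266760e-05    FALSE
```

The maximum-likelihood sequence recovers the planted order of the
remaining events exactly (log-likelihood −9495.86; the MCMC positional
variance diagram is the identity, i.e. the ordering is certain at these
separations):

```
  position       region
1        1      putamen
2        2      caudate
3        3     pallidum
4        4    insula_wm
5        5          csf
6        6     amygdala
7        7 optic_chiasm
```

Staging separates the groups — controls sit in the lower half of the
stages, manifest subjects in the upper half, premanifest subjects span
both — and the phenotype regressions recover the planted stage-linked
slopes (TMS +0.98, SDMT −1.0, Stroop −1.4, CAP +0.014) within error:

```
  group lower upper          phenotype   slope     se       p   n
1    HC  0.99  0.01        1       TMS  1.0300 0.1100 1.6e-18 238
2 preHD  0.42  0.58        2      SDMT -1.0000 0.1900 4.5e-07 238
3    HD  0.06  0.94        3    Stroop -1.6000 0.3400 4.6e-06 238
                           4       CAP  0.0192 0.0035 7.2e-08 238
```

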