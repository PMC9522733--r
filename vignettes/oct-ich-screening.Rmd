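---
title: "Screening for intracranial hypertension with peripapillary OCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for intracranial hypertension with peripapillary OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octscreen)
```

## The problem

Premature fusion of the sagittal suture (the most common single-suture
craniosynostosis) can restrict intracranial volume and raise intracranial
pressure. Established screening relies on fundoscopy, which detects
papilledema late, subjectively, and with poor granularity for follow-up.
Peripapillary OCT measures total retinal thickness (TRT, μm) and total
retinal volume (TRV, mm³) on an eight-sector grid around the optic disc —
objective quantities that rise with intracranial hypertension (ICH) — but
using them as a screen requires pediatric normative ranges, principled
cut-off classification, and association tests against the clinical signs
that proxy ICH (skull growth arrest, radiographic fingerprinting,
headache). `octscreen` packages that analysis end to end.

## The sector grid and derived indices

The grid centres circles of diameter 1, 2 and 3 mm on the optic disc. The
annulus between 1 and 2 mm is the *inner ring* (sector prefix "2"), between
2 and 3 mm the *outer ring* (prefix "3"); each ring splits into superior,
nasal, inferior and temporal quadrants — eight sectors per eye, each with a
thickness and a volume. Derived indices are plain means: the overall mean
over available sectors, ring means over the four sectors of a ring, and a
quadrant value as the mean of the quadrant's inner and outer sector. The
quadrant aggregate is not given an explicit definition in the source
literature for this grid; the inner/outer mean is the only symmetric choice
consistent with the grid geometry, and it is what `derive_indices()`
computes. The central 1-mm disc area is not used.

Missing sectors are excluded from each mean — never imputed — and an index
whose constituent sectors are all missing is itself missing. A scan with
fewer than 6 of 8 sectors (less than 75%) is excluded outright; exactly 6
is kept, reading "less than 75%" strictly.

Sector volume relates to thickness through the annulus geometry:
`volume = thickness/1000 × area(ring)`, with quadrant areas
π(1² − 0.5²)/4 ≈ 0.589 mm² (inner) and π(1.5² − 1²)/4 ≈ 0.982 mm² (outer).
At a 378 μm retina this predicts ≈ 0.30 mm³ mean sector volume, matching
the normative medians' scale — a coherence the synthetic generator relies
on.

One eye per subject enters each analysis. Controls contribute the right
eye (left only when the right scan is missing or fails quality), the
convention of normative ophthalmology studies; patients contribute the eye
with the highest mean TRT, since papilledema can be unilateral.

## Reference intervals

The reference interval (RI) is the central 95% of the healthy
distribution, the clinical-chemistry convention: point endpoints are the
empirical 2.5th and 97.5th percentiles, computed by linear interpolation at
rank `1 + (n − 1)q` (`empirical_quantile()`); the convention matters at
reference-interval sample sizes and is therefore fixed and documented.

Each endpoint carries its own 95% confidence interval from a seeded
bootstrap (default 2000 resamples). The CI uses *kernel-smoothed*
resampling: each resampled value receives Gaussian noise at the Silverman
bandwidth `0.9 min(s, IQR/1.34) n^{-1/5}` before the endpoint is
recomputed, and the CI is the 2.5th/97.5th percentile of the bootstrap
endpoint distribution. The smoothing is not cosmetic: the plain bootstrap
distribution of an extreme order statistic at n ≈ 64 is supported on a
handful of values, and the unsmoothed percentile CI covers the true
quantile only ~78% of the time in our Gaussian simulations, versus ~95%
with smoothing (basic and normal-interval constructions also undercover,
at ~77% and ~86%). `ci_method = "percentile"` restores the unsmoothed
variant for comparison. With n = 64, the type-7 point estimate of an
extreme quantile is biased inward by roughly 8 μm at σ = 63; this is a
property of the estimator, shrinks with n, and is why endpoint CIs — not
just points — are reported.

Covariate screening uses median regression (check-loss minimisation via
epsilon-regularised IRLS) of each index on age, sex and mild refractive
error, with case-resampling bootstrap CIs and p-values sharing the seeded
engine. When none of the covariates shows an effect, the normative cohort
is pooled — the package deliberately offers no age- or sex-partitioned
intervals. The Shapiro–Wilk check (`assess_normality()`) is advisory only
and never gates the non-parametric RI.

## Classification

Cut-offs are the computed RI endpoints at full precision. Flags use strict
inequalities — a value exactly at an endpoint is normal — so a published
cut-off pair like (256.0, 503.8) flags "increased" only above 503.8. The
overall OCT is abnormal when mean TRT *or* mean TRV is increased; OR-logic
is the default because thickness and volume elevation almost always
coincide but a discordant case should not be silently dropped, and
`logic = "and"` is available. Subjects with pseudopapilledema (a
high-hyperopia mimic of papilledema) are retained in the primary
fundoscopy cross-tab but excluded from the clinical-sign associations —
their elevation has a known non-ICH cause.

## Clinical signs

**Skull growth arrest.** Occipitofrontal circumference (OFC) is converted
to SD-scores against a growth reference (linear interpolation of mean and
SD in age; no extrapolation). Arrest is a fall of 0.5 SD or more over 2
years; exactly 0.5 counts. The baseline anchors at the first
post-surgical observation, with linear interpolation to the exact 2-year
mark when no visit falls there. Because trajectories often span more than
2 years, the default evaluates every 2-year window starting at an
observation (any qualifying window ⇒ arrest); `sliding = FALSE` restores
the single baseline window. Fewer than 2 points or less than 2 years of
follow-up give an indeterminate verdict, not a negative.

**Fingerprinting.** Two raters score radiographs 0/1/2; only extensive
fingerprinting (2) is abnormal, so the scale collapses 0,1 → 0 and 2 → 1.
Post-collapse disagreement is flagged for consensus review rather than
auto-resolved. Interrater agreement is Cohen's κ with the
Fleiss–Cohen–Everitt asymptotic variance; the CI is reported untruncated
by default because the truncation hides how uninformative a small sample
is (a κ CI can legitimately print an upper bound above 1), with
`truncate = TRUE` available.

## Exact 2×2 machinery

Tables are oriented rows = (exposure −, exposure +), columns =
(outcome −, outcome +), so the odds ratio is ad/bc and OR > 1 means the
exposure associates with the outcome. Conditional on both margins, the
diagonal cell follows Fisher's noncentral hypergeometric law with
parameter ψ equal to that odds ratio; all masses are computed in log
space.

Three choices align the output digit-for-digit with the classical
exact-test software family, which is what published values in this field
come from:

- the **estimate** is the conditional MLE, the root of E<sub>ψ</sub>[K] = a,
  found as that software finds it — on ψ ∈ (0, 1] directly or on 1/ψ above
  1, at the standard root tolerance (`tol = .Machine$double.eps^0.25`,
  configurable downward; at large ψ the loose default can differ from the
  exact root by more than the printed precision, and reproducing printed
  values requires reproducing the convention);
- the **p-value** is two-sided by the point-probability criterion, summing
  all masses not exceeding the observed one, with a 1e-7 relative slack
  guarding floating-point ties;
- the **CI** (default `"minlike"`) inverts that two-sided test: the
  interval is the set of ψ whose two-sided p is ≥ 0.05. The `"central"`
  method — two one-sided tails at α/2, the other classical convention — is
  also provided; it is systematically wider.

Boundary counts give one-sided results (OR 0 or ∞, CI open on that side);
a degenerate margin reports not-applicable rather than erroring. The
rank-sum and paired-t comparisons wrap the standard library tests (exact
enumeration for small tie-free samples, tie-corrected normal approximation
with continuity correction otherwise).

## The synthetic cohort generator

The generator exists so every downstream stage is testable without patient
data. What it emulates, and the defaults' rationale:

- **Controls** (n = 64): per-sector thickness = 380 μm + a fixed sector
  profile + subject effect + eye effect + sector noise (20 μm). The
  subject-level SD of mean TRT is 63 μm, chosen once from the normative
  range's half-width (≈ 124 μm ≈ 1.96 σ) — consistent with a Gaussian
  shape, whose adequacy the Shapiro–Wilk screen of real data supported.
  The sector profile is anchored at the midpoints of the published
  per-sector ranges, so ring and sector means sit in realistic relative
  positions. Two eyes correlate at 0.9.
- **Patients** (n = 93): a +24 μm median shift; a latent ICH state
  (prevalence 0.12) adds a large elevation (150 μm × U(0.8, 1.2)) and
  drives fundoscopic papilledema (overall prevalence 0.043) and the
  clinical signs via conditional probabilities (arrest 0.50 vs 0.03,
  fingerprinting 0.57 vs 0.23, headache 0.27 vs 0.07, given ICH vs not).
  This causal layering is an *invention of the generator* — real data do
  not come with a latent ICH label — introduced so the sign cross-tabs
  are non-degenerate and recovery is testable against truth.
- **Pseudopapilledema** (prevalence 0.022) gets high hyperopia (≥ +4 D)
  and a thickness-only elevation: its sector volumes follow the
  *unelevated* thickness, reproducing the clinically observed
  thickness/volume discordance.
- **Volumes** derive from thickness via the annulus geometry times
  `exp(N(0, 0.03))`, keeping every sector within 15% of its
  thickness-implied volume.
- **Trajectories**: arrest-positive patients decline linearly by 0.7–1.2
  SD per 2 years; others oscillate within ±0.3 SD; both with small
  observation noise, 4–8 visits from a post-surgical baseline to the scan
  age. Converted to centimetres against the packaged growth reference —
  a smooth *synthetic* stand-in (not a national standard), replaceable by
  any table in the same CSV schema.
- **Determinism**: one master seed; each subject draws from a
  counter-based substream, so enlarging a cohort never reshuffles earlier
  subjects, and identical configs give byte-identical CSVs.
- Sign missingness (arrest 3%, fingerprinting 40%, headache 25%) mirrors
  the varying denominators such studies report.

What the generator does *not* model: between-sector correlation structure
beyond the shared subject/eye effects, age or sex effects on thickness
(deliberately null, matching the pooled normative design), longitudinal
retinal dynamics, or OCT imaging artefacts. Passing tests therefore show
the *pipeline* recovers what the generative model encodes — they are not
evidence about device behaviour or real-cohort effect sizes.

## Numerical choices and degenerate inputs

- Quantile convention: type-7 interpolation, stated above; the bootstrap
  reuses it for CI percentiles.
- Root-finding for ψ: bracketed `uniroot` on the unit/reciprocal scales;
  CI roots are bracketed at the continuity-corrected sample OR and solved
  to 1e-10 on the log scale.
- Reference intervals require n ≥ 20 and warn below 40; all-missing
  parameters are reported with their missing count rather than dropped
  silently.
- Constant samples: RIs degenerate to zero width; Shapiro–Wilk and κ
  report not-applicable; identical paired eyes give t = 0, p = 1, and a
  constant nonzero eye difference gives p = 0 with a degeneracy flag.
- Ages are decimal years; trajectory ages must be strictly increasing.

## Problem sizes in the test-suite simulations

The property simulations use sizes chosen to make their Monte-Carlo noise
small relative to the tolerance being asserted: 200 replicate cohorts of
n = 64 (with 2000 bootstrap resamples each) for RI bias and endpoint-CI
coverage; n = 2000 for median-regression recovery within ±0.3; n = 500
patients for arrest-detector sensitivity/specificity ≥ 0.95; exhaustive
enumeration of every 2×2 table with margins up to 12 for the exact-test
identities.

## Known limitations

- The normative engine pools all ages 4–10 and both sexes; if a real
  cohort shows covariate effects in the median-regression screen,
  partitioned intervals would be needed and are out of scope here.
- The conditional-MLE odds ratio is reported at the classical software
  tolerance by default; pass `tol` explicitly for the mathematically
  tight root.
- The packaged growth reference is synthetic; arrest verdicts on real
  data require a real national standard in the same schema.
- Exact-test CIs for tables with 4 events are extremely wide; that is the
  statistics, not a bug.
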