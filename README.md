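# octscreen

Screening children with sagittal suture synostosis for intracranial
hypertension (ICH) is hard: fundoscopy detects papilledema late and
subjectively, while invasive intracranial-pressure monitoring is reserved
for selected cases. Peripapillary optical coherence tomography (OCT) offers
an objective alternative — total retinal thickness (TRT, μm) and total
retinal volume (TRV, mm³) rise with intracranial pressure — but pediatric
normative data for these automatically segmented indices are scarce.

`octscreen` implements the full screening analysis for clinicians and
biostatisticians working with such cohorts:

- **Normative reference intervals.** For each parameter of the eight-sector
  peripapillary grid (circle diameters 1/2/3 mm; inner and outer annulus ×
  superior/nasal/inferior/temporal), the central 95% reference interval
  (RI) is estimated by the empirical quantiles
  `q(α/2)`, `q(1 − α/2)` of a healthy cohort, with a confidence interval
  for each endpoint from a non-parametric (kernel-smoothed) bootstrap.
- **Covariate screening.** Median (quantile) regression of each index on
  age, sex and mild refractive error, with seeded bootstrap inference —
  the check that justifies pooling the normative cohort.
- **Cut-off classification.** Patient scans are flagged
  `decreased`/`normal`/`increased` per parameter by strict comparison with
  the RI endpoints; the overall OCT is abnormal when mean TRT or mean TRV
  is increased. Pseudopapilledema (high hyperopia, drusen) is excluded
  from secondary analyses.
- **Clinical signs.** Skull growth arrest (a fall of ≥ 0.5 SD in the
  occipitofrontal-circumference SD-score over 2 years, with interpolation
  and an optional sliding window), collapse of the 3-point fingerprinting
  scale (only *extensive* fingerprinting is abnormal), and Cohen's κ for
  interrater agreement.
- **Exact association statistics.** For each 2×2 cross-tab the package
  computes the conditional maximum-likelihood odds ratio (the root of
  E<sub>ψ</sub>[K] = a under Fisher's noncentral hypergeometric law), the
  exact confidence interval by two-sided test inversion, and the two-sided
  point-probability p-value — the conventions of classical exact-test
  software, reproduced digit-for-digit.
- **Synthetic cohorts.** A calibrated generator emulates the study
  setting (control TRT ≈ 380 ± 63 μm, patient shift ≈ +24 μm, a latent ICH
  state driving papilledema, thickness elevation and clinical signs), so
  the entire pipeline is testable without patient data.

## Worked example

```r
library(octscreen)

# a synthetic study: 64 controls, 93 patients, fully seeded
cfg <- generator_config(seed = 1)
sim <- generate_cohort(cfg)

# normative reference intervals from the controls
ri <- reference_interval_table(sim$cohort, n_bootstrap = 2000, seed = 1)
subset(ri, parameter == "mean_trt")
#>   parameter lower_ri lower_ci_low lower_ci_high upper_ri upper_ci_low upper_ci_high  n n_missing
#> 1  mean_trt 246.7219     208.3632      294.0986 485.0786      469.813      534.1966 64         0

# classify the patients against the cut-offs and test the association
# between an abnormal OCT and papilledema on fundoscopy
flags <- classify_cohort(sim$cohort, cutoffs_from_reference_intervals(ri))
table(flags$overall_oct)
#>   abnormal normal
#>         23     70

fisher_exact(table2x2(76, 13, 1, 3))
#> Exact 2x2 test: OR (conditional MLE) = 16.68, 95% CI [1.708, 458.2], p = 0.01539
#>   sample OR = 17.54; CI method = minlike
```

The reference interval above says: the central 95% of healthy mean TRT in
this simulated cohort runs from ~247 to ~485 μm, and the upper endpoint
itself is known to within roughly ±30 μm at n = 64. The exact test says a
patient with papilledema has ~17-fold higher odds of an increased TRT, with
the very wide CI typical of 4 papilledema cases.

The same analyses run end-to-end with `run_pipeline(run_config(seed = 1,
output_dir = "report"))`, which writes the covariate screen, the normative
table, the three association tables and a run log; a thin command-line
front end lives at `inst/cli/octscreen.R`.

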