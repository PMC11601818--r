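# ch4norm

Subtyping Parkinson's disease with mild cognitive impairment (PD-MCI)
by MRI evidence of cholinergic nucleus 4 (Ch4) degeneration.

Ch4 — the cell group forming most of the nucleus basalis of Meynert —
is the main cholinergic projection to cortex, and its degeneration is a
leading candidate mechanism for cognitive decline in Parkinson's
disease. `ch4norm` implements the analytic chain that turns
voxel-based-morphometry output into a Ch4-based PD-MCI subtype and its
clinical validation:

* **Region GMD extraction** — grey-matter density of a region as the
  probabilistic-mask-weighted mean of a normalized, modulated GM map:
  `GMD = Σ g_v w_v / Σ w_v` (`computeRegionGMD()`), with strict grid
  compatibility checks and NIfTI-1 I/O.
* **Regression-based norming** — healthy-control GMD is converted to
  scaled scores `s = 10 + 3 (x − x̄_HC)/sd_HC`, regressed on age, sex,
  scanner (GE/Philips vs Siemens) and TIV, and each patient's deviation
  is standardized by the reference RMSE:
  `z = (s_actual − s_predicted)/RMSE`; **low Ch4** iff `z ≤ −1`
  (`fitNormingModel()`, `adjustedZ()`).
* **Data-driven subtyping** — diffuse malignant / intermediate / mild
  motor predominant labels from duration-specific 75th-percentile rules
  over the composite motor score (UPDRS-II + III) and three non-motor
  axes (SCOPA-AUT, RBDSQ, cognitive burden 30 − MoCA)
  (`computeSubtypeThresholds()`, `assignSubtype()`).
* **Cognitive-milestone survival** — six milestones (MoCA < 21; UPDRS
  items 1.1/1.2/1.5 ≥ 3; clinical and composite dementia), first-passage
  detection on the visit grid, Kaplan-Meier, log-rank, and a Cox model
  adjusted for age, sex and baseline MoCA (`buildMilestoneEvents()`,
  `coxMilestones()`).
* **Group statistics** — median/IQR + Kruskal-Wallis for continuous
  variables, uncorrected Pearson chi-square for binarized symptom items,
  and the noncentral-t two-sample power calculation
  (`compareGroups()`, `twoSamplePower()`).
* **Synthetic cohorts** — a generator with planted ground truth
  (171 HC, 148 PD-MCI with a latent 32/148 low-Ch4 subgroup, 6-month
  visits, exponential proportional hazards with HR 1.95) so the entire
  pipeline runs and is validated without restricted data
  (`simulationConfig()`, `generateHCCohort()`, `generatePDMCICohort()`).

`runFullPipeline()` orchestrates everything from a single config and
writes per-stage outputs plus a reproducibility manifest.

## Worked example

```r
library(ch4norm)

cfg   <- simulationConfig(seed = 1)          # the default study conditions
hc    <- generateHCCohort(cfg)               # 171 healthy controls
model <- fitNormingModel(hc)
sim   <- generatePDMCICohort(cfg)            # 148 PD-MCI + visits + truth
pd    <- adjustedZ(sim$cohort, model)
table(pd$ch4_group)
#>    low normal
#>     58     90

ev <- merge(buildMilestoneEvents(sim$visits),
            pd[c("subject_id", "ch4_group")], by = "subject_id")
ev$group <- ev$ch4_group
logrankTest(ev)
#> log-rank chi2 = 2.33, p = 0.1269

cv <- pd[c("subject_id", "age", "sex", "moca")]
cv$low_ch4 <- as.integer(pd$ch4_group == "low")
coxMilestones(ev, cv)$coefficients   # low_ch4 row:
#> HR 1.14 (95% CI 0.72-1.79), p = 0.574

compareGroups(pd, continuous = c("scopa_aut", "upsit"),
              items = "updrs_1_2")
#>    variable              group1              group2    p_value
#> 1 scopa_aut  17.00 (9.25-20.75)  12.00 (8.00-18.75) 0.02178332
#> 2     upsit 21.50 (15.00-27.75) 23.00 (17.00-27.75) 0.13620339
#> 3 updrs_1_2       29.3% (17/58)       31.1% (28/90) 0.81615982
```

Reading the numbers: of 148 simulated PD-MCI subjects, 58 are labelled
low Ch4 (the 32 planted lows plus the expected ~16% normal-tail false
positives at the z ≤ −1 cut). The low group shows the planted worse
autonomic burden (SCOPA-AUT median 17 vs 12, p = 0.022). At this
single-study size the survival contrast between the *classified* groups
is attenuated by classification noise (HR 1.14 here vs the planted 1.95
for the *latent* groups); the test suite demonstrates that the Cox
machinery recovers the planted log-HR without bias once classification
noise is removed and n grows (500 replicates at n = 2000).

Single quantities reproduce published summary statistics directly:

```r
twoSamplePower(116, 32, d = 0.56)      # 0.7956  -> 80% power
pearsonChi2(15, 116, 9, 32)$p_value    # 0.0390  -> apathy p = 0.04
```

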