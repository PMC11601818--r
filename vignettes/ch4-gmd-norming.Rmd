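---
title: "Methods: Ch4 grey-matter-density norming and PD-MCI subtyping"
author: "ch4norm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ch4 grey-matter-density norming and PD-MCI subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ch4norm)
```

## The problem

Mild cognitive impairment in Parkinson's disease (PD-MCI) is clinically
heterogeneous. One candidate axis for splitting it into more homogeneous
subgroups is degeneration of cholinergic nucleus 4 (Ch4), the cell group
comprising most of the nucleus basalis of Meynert, whose cortical
cholinergic projections support attention and memory. Ch4 integrity can
be indexed on structural MRI as the grey-matter density (GMD) inside a
histology-derived probabilistic map of the nucleus, applied to
spatially normalized, modulated grey-matter segmentations from a
voxel-based-morphometry (VBM) pipeline.

`ch4norm` implements the full analytic chain downstream of VBM
preprocessing: region GMD extraction, regression-based normative
z-scoring against a healthy-control (HC) reference, low/normal Ch4
classification, data-driven clinical subtyping, cognitive-milestone
survival analysis, and the associated group statistics. A synthetic
cohort generator with planted ground truth makes every stage testable
without access to restricted clinical data.

## Region GMD

For a grey-matter map $g$ and mask weights $w$ on the same voxel grid,

$$\mathrm{GMD} = \frac{\sum_v g_v\, w_v}{\sum_v w_v}.$$

The weighted sum is standardized by the total mask weight, so the value
is a weighted mean, invariant to rescaling the mask, and bounded by the
map's values over the mask support. Grids must match exactly: shapes
equal and affines equal to within an absolute per-element tolerance of
`1e-4` (enough to absorb float serialization noise, nothing more).
Mismatched grids are an error — silent resampling would change GMD
values irreproducibly, so it is never done. Whether the map is smoothed
or unsmoothed is the caller's choice; the extraction is agnostic. Mask
voxels outside any brain mask are included as supplied.

`computeTIV()` is a plain tissue-sum estimate
($\sum (gm + wm + csf) \times$ voxel volume) provided for self-contained
synthetic runs; in a real analysis TIV usually arrives as a covariate
column from the segmentation software, and the pipeline treats the
table column as authoritative.

## Regression-based norming

Raw Ch4 GMD is first anchored to the HC reference as a *scaled score*
with reference mean 10 and SD 3:

$$s = 10 + 3\,\frac{x - \bar{x}_{HC}}{\mathrm{sd}_{HC}}.$$

The transform is linear (not rank-based), chosen for invertibility and
because it makes the reference-sample mean and SD exactly 10 and 3, a
property the tests assert to machine precision; values are carried
unrounded. The scaled scores are regressed by OLS on age, sex
(male = 1), scanner indicators for GE and Philips (Siemens is the
reference level, implied by the model naming only GE and Philips
offsets), and TIV in mL:

$$\hat{s} = c + b_{age}\,\mathrm{age} + b_{sex}\,\mathrm{sex} +
  b_{GE}\,I_{GE} + b_{phil}\,I_{Philips} + b_{tiv}\,\mathrm{TIV}.$$

A subject's adjusted z-score is $z = (s - \hat{s})/\mathrm{RMSE}$, where
the RMSE is the residual SD of the HC fit with denominator $n - p - 1$
($p = 5$); the denominator choice is recorded in the model file so the
alternative ($n$) is auditable. Subjects are classified **low Ch4** iff
$z \le -1$ (inclusive boundary) and **normal** otherwise; the threshold
is exposed in the API but defaults to $-1$.

Consequences used as test invariants: on the reference sample the mean
of $z$ is exactly 0 (OLS residuals with an intercept sum to zero) and
its SD is exactly $\sqrt{(n-6)/(n-1)}$; classification is monotone in
raw GMD at fixed covariates; under the null a large held-out HC sample
is labelled low at rate $\Phi(-1) \approx 15.87\%$. Missing covariates
are an error, never imputed — the norm is only valid for complete
covariate vectors. Models serialize to JSON with 17 significant digits
so a reloaded model reproduces bit-identical z-scores.

## Data-driven subtyping

The composite motor score is MDS-UPDRS-II + MDS-UPDRS-III. The three
non-motor axes are SCOPA-AUT, RBDSQ, and a cognitive axis. Because low
MoCA means worse cognition while the rule is phrased in terms of
*exceeding* percentiles, the cognitive axis is defined as burden
$= 30 - \mathrm{MoCA}$: exceeding its 75th percentile is equivalent to
MoCA below its own 25th percentile. This directional choice is the one
genuinely open reading of the rule and is flagged prominently here and
in the function documentation.

Within each disease-duration bin, the 75th percentile of each axis is
computed with the linear-interpolation quantile definition (R type 7;
recorded in the threshold metadata). Labels follow strict inequalities,
taken literally:

* **diffuse malignant** — motor $>$ its threshold AND $\ge 1$ non-motor
  axis above, OR all 3 non-motor axes above;
* **mild motor predominant** — motor $<$ its threshold AND all 3
  non-motor axes below;
* **intermediate** — everything else. Exact ties satisfy neither strict
  inequality and therefore fall to intermediate.

The three labels partition the input space; with independent
continuous scores and a single bin, exact enumeration over the 16
exceedance-flag combinations gives
$P(\text{mild}) = 0.75^4 \approx 0.3164$ and
$P(\text{malignant}) = 0.25(1 - 0.75^3) + 0.75 \cdot 0.25^3 = 0.15625$,
which the acceptance tests verify by simulation at $n = 10^5$.

Duration bins are not prescribed by the subtype definition beyond being
"duration specific"; the default is cohort duration tertiles with a
minimum of 20 subjects per bin (unstable percentiles are refused, not
warned about), overridable in the API.

## Cognitive milestones and survival

Six milestones define cognitive progression: MoCA $< 21$; MDS-UPDRS
items 1.1, 1.2, 1.5 $\ge 3$; clinical dementia diagnosis; and composite
dementia categorization (consumed as a precomputed boolean because its
per-domain thresholds are assessor-defined). A subject's event time is
the earliest visit at which *any* criterion holds — a single qualifying
visit suffices (persistence is not required), the baseline visit
counts (baseline qualifiers get time 0 and a flag rather than being
dropped), and subjects with no qualifying visit are censored at their
last visit. When several criteria first hold at the same visit the
reported type follows the fixed documented order (MoCA, item 1.1, 1.2,
1.5, clinical dementia, composite dementia); the event time is
unaffected.

Kaplan-Meier curves, the 1-df log-rank test and the multivariable Cox
model go through the `survival` package. The Cox model adjusts for
baseline age, sex and baseline MoCA alongside the low-Ch4 indicator;
"baseline" MoCA is a documented assumption. Ties are certain on a
6-month visit grid, so the Efron approximation is the default, with
Breslow behind a flag. Constant covariates and non-convergence are
errors, not silent output. Tests cross-check the implementation against
hand-coded oracles: an observed-minus-expected log-rank tabulation and
a grid-search maximization of the partial likelihood on small untied
instances.

## Group statistics

Continuous variables are described as median (IQR, interpolated
quartiles) and compared with the Kruskal-Wallis test (used even for two
groups); 0-4 symptom items are binarized at $\ge 1$ and compared with
the *uncorrected* Pearson chi-square. The absence of a continuity
correction is deliberate and verified: the published p = 0.06 for a
0/116 vs 1/32 split is reproduced only by the uncorrected statistic.
Fisher's exact test is available behind an explicit flag, as is the
choice to forgo multiplicity correction (none is applied by default,
matching the source analysis). Study power uses the exact noncentral-t
two-sample power with noncentrality $d/\sqrt{1/n_1 + 1/n_2}$.

## The synthetic cohort generator

The generator's defaults are the study conditions: 171 HC for norming;
148 PD-MCI of whom a latent 32/148 are low-Ch4; age 60.6 ± 11.6 years
truncated at 30 (the cohort entry criterion); 61.4% male; TIV
1450 ± 130 mL; scanner mix Siemens/GE/Philips 0.6/0.2/0.2 (no site mix
is published; this is a plausible multicenter split, fixed once). HC
GMD follows the planted linear model with residual SD 0.025 around a
GMD scale of ~0.45. The latent low subgroup's GMD is shifted by −0.05
(two residual SDs, enough for the z-rule to recover most latent lows
while keeping realistic misclassification), and its clinical scores are
shifted toward the published direction of worse severity (e.g.
SCOPA-AUT +6, UPSIT −6), with magnitudes loosely matched to the
published group medians — an emulation, not a calibration. Clinical
scores are rounded, range-clipped normals (MoCA clipped to the 21-26
PD-MCI inclusion band, items to 0-4): ordinal realism with simple
parameters.

Time to first milestone is exponential proportional hazards: baseline
hazard 0.008/month, log-HR $\ln 1.95$ for the latent low group (an
emulation default mirroring the published hazard ratio, not a
reproduction claim), small centred age/sex/MoCA effects, exponential
dropout at 0.002/month and administrative censoring at 96 months. The
continuous latent time is kept in the truth object; the observed event
is interval-detected at the first 6-month visit at or after it, which
is how such assessments actually occur. Visit rows before the event
never cross a criterion; at and after it the subject's randomly chosen
milestone type is planted, so detection recovers the grid time exactly
— detection correctness and grid-mapping are then separately testable.

Truth separation is an invariant: analysis functions never read the
truth object; only tests compare estimates against it.

What the generator does **not** emulate: real whole-brain anatomy or
scanner artifacts, item-level correlation structure of the clinical
instruments, non-proportional hazards, informative dropout, missing
data, or site effects beyond the scanner intercepts. Passing tests
therefore demonstrate correctness of the analytic machinery under the
stated generative model, not robustness to every feature of real
cohort data.

## Numerical choices and problem sizes

* Quantiles: linear interpolation (type 7) everywhere, recorded in
  threshold metadata.
* Affine tolerance `1e-4` absolute per element; planted-image GMD
  recovery asserted to `1e-10`.
* JSON serialization carries 17 significant digits, making
  fit → save → load → score bit-reproducible.
* Validation problem sizes (chosen to bound Monte-Carlo error while
  keeping the default suite fast): OLS coefficient recovery at
  $n = 5000$ within 3 SE; null low-Ch4 rate at $n = 20000$ within
  ±1 percentage point of $\Phi(-1)$; Cox recovery over 500 replicates
  of $n = 2000$ (mean log-HR within 0.05 of $\ln 1.95$, CI coverage in
  [93%, 97%]); log-rank type-I error over 1000 null replicates within
  (0.03, 0.07); subtype frequencies at $n = 10^5$ within 4 binomial
  SEs of the enumeration values.
* The null type-I simulations zero the clinical shifts as well as the
  group log-HR, because a shifted baseline MoCA would otherwise reach
  the hazard through the MoCA coefficient — a genuine group difference,
  not a null.

## Known limitations

* VBM preprocessing (registration, segmentation, modulation,
  smoothing) is out of scope; inputs must already be in a common
  space. The extraction refuses, rather than resamples, mismatched
  grids.
* The composite-dementia milestone is consumed as a boolean column;
  the package does not operationalize its per-domain thresholds.
* T-scored neuropsychological columns pass through untouched; their
  external norms are not re-derived.
* The percentile-rule subtyping implemented here is the
  duration-specific 2017 operationalization; the older cluster-derived
  subtyping is not included.

## A worked end-to-end run

```{r, eval = FALSE}
cfg <- pipelineConfig(tempfile("run"), simulationConfig(seed = 1))
man <- runFullPipeline(cfg)
man$ch4_groups     # low / normal split of the 148 PD-MCI subjects
```

The run directory contains the fitted norming model, scored and
subtyped cohort tables, milestone events, Kaplan-Meier curves, log-rank
and Cox results, the group-comparison table, and a manifest with the
config hash and per-stage row counts; a rerun with the same config is
bit-identical.
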