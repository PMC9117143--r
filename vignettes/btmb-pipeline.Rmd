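---
title: "Methods: bTMB scoring and biomarker-stratified trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bTMB scoring and biomarker-stratified trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btmbtools)
library(dplyr)
```

`btmbtools` re-implements, as open and tested code, the computational
chain of a biomarker-stratified single-arm trial of blood tumor
mutational burden (bTMB) in advanced non-small cell lung cancer: scoring
plasma variant calls into a per-patient burden, stratifying efficacy
endpoints by the burden, adjusting a low-ctDNA subgroup comparison by
inverse probability weighting, and exploring the mutated-gene landscape.
This vignette records the models, the parameters that matter, the
numerical choices, and what the synthetic-data validation does and does
not establish.

## The scoring model

A plasma sample is a table of variant calls with allele frequencies
(AF). Scoring proceeds in three steps.

**Germline filtering.** Plasma sequencing sees both tumor-derived and
inherited variation. Calls present in population databases (dbSNP/ExAC
style membership, carried as the `in_population_db` flag) are germline.
Rare germline variants absent from databases are recognised by a
zygosity surrogate: in plasma, germline variants cluster near allele
fraction 0.5 (heterozygous) or 1.0 (homozygous), while tumor-derived
fragments are diluted to low fractions. `classify_germline()` therefore
flags calls with AF within `af_germline_band` (default ±0.05) of 0.5,
or above 1 − band, as germline. Proprietary somatic-germline-zygosity
classifiers use read-level evidence we do not model; the band rule is an
explicit, configurable stand-in, and everything downstream treats the
resulting `germline_flag` as given.

**Tumor-fraction gating.** The maximum somatic allele frequency (MSAF)
is the highest AF among somatic-flagged substitutions below 20%; calls
at or above 20% are excluded as likely unflagged germline or clonal
hematopoiesis, while driver status does *not* exclude a call. MSAF
proxies the circulating tumor fraction; samples with MSAF < 1% are
non-evaluable because the assay cannot distinguish a quiet tumor from
insufficient ctDNA. Non-evaluable samples report their MSAF but mask the
burden score, mirroring how a biomarker-evaluable population is defined.

**Counting.** The bTMB score counts distinct somatic single-nucleotide
substitutions with AF ≥ 0.5% (inclusive) that are not known drivers —
drivers are removed because the capture panel is enriched for them,
which would otherwise bias the count. Insertions and deletions are never
counted. Distinctness is per `(position, ref, alt)` key within a sample:
whether repeated substitutions at one position should count separately
is not externally specified, so the package counts unique keys and
documents it. The ≥ 0.5% validation bound is applied after germline
filtering (the order is not externally specified either; filtering first
is the conservative reading since the germline flag does not depend on
the AF floor). The score divided by the panel footprint (1.1 Mb for the
default 394-gene panel) gives mutations per megabase: a score of 16 is
14.5 mut/Mb at one decimal, with half-away-from-zero rounding used for
all reported percentages and decimals, matching journal convention.

## The efficacy statistics

All statistical primitives the trial design calls for are implemented
from first principles; the `survival` package appears only in the test
suite as an independent cross-check.

* **Blaker exact interval** for response rates: inverts the two-sided
  acceptability function, giving an exact interval never wider than
  Clopper–Pearson. Bounds are located by nested 64-point grid refinement
  of the acceptability function between the Clopper–Pearson envelope and
  the point estimate, to a default tolerance of 1e-6 on the probability
  scale. The acceptability function is discontinuous, so refinement
  tracks the first grid point inside the region rather than assuming
  monotonicity.
* **Cochran–Mantel–Haenszel** response test: the classical pooled
  statistic; with one stratum it reduces to the Pearson chi-square
  scaled by (N−1)/N, without continuity correction (the trial names the
  test but no correction; the uncorrected form is the common default).
* **Rate differences** use the unpooled Wald interval at 90%; **odds
  ratios** use the Woolf logit interval with Haldane–Anscombe 0.5
  correction on zero cells. Neither construction is named in trial
  reports; both were chosen because they reproduce the published
  intervals from the reconstructed counts, verified as a derivation step
  before the tests were frozen.
* **Kaplan–Meier** curves process censorings after events at tied
  times; the Greenwood variance is accumulated on the plain survival
  scale, with variance taken as 0 once the curve is exhausted.
  **Brookmeyer–Crowley** median intervals invert the chi-square test
  `(S(t) − 0.5)² / Var[S(t)] ≤ χ²₁` over the event-time grid and report
  the hull of the acceptance set; a side that the follow-up cannot bound
  is reported as not estimable.
* **Landmark survival intervals** use the Greenwood variance on the
  plain scale, clipped to [0, 1]; a complementary log-log transform is
  available by flag and preferable near the boundaries.
* **Log-rank** tests are the standard unweighted form; for small
  cohorts an exact permutation p-value (exhaustive over label
  reassignments) is available, used to validate the asymptotic form.
* **Cox hazard ratios** maximise the partial likelihood for a binary
  group by Newton's method with step halving (tolerance 1e-9 on the
  log-likelihood, 25 iterations, divergence beyond |β| > 15 flagged as
  monotone likelihood with an unbounded interval). Efron tie handling is
  the default, Breslow by flag; both match `coxph` to machine precision
  in the tests. Case weights replace unit counts in all risk sums,
  giving the weighted Cox model the IPW analysis needs. Hazard ratios
  are oriented high-vs-low so HR < 1 favours the biomarker-high group;
  the orientation is stated because it is easy to flip silently.
* **Power** uses Schoenfeld's approximation. With the design inputs —
  150 patients, 24% biomarker-high prevalence, two-sided α = 0.10 and
  a mature endpoint (we take 90% of patients with an event, a realistic
  maturity for progression in this setting) — the formula gives 81%
  power to detect a hazard ratio of 0.6, matching the stated design.

Confidence levels follow the trial conventions: 95% for response rates
and medians, 90% for hazard ratios and rate differences; every function
takes its level as an argument since the level for landmark estimates is
not externally specified.

## The cutoff sweep

`btmb_cutoff_sweep()` recomputes group sizes, response rates, rate
differences, CMH p-values, PFS/OS hazard ratios and Brookmeyer–Crowley
medians at score cutoffs 10–20 by 2. Non-evaluable patients are excluded
throughout, so group sizes are complementary and the high groups are
nested as the cutoff rises. A cutoff that empties a group flags the row
rather than failing the sweep.

## The IPW adjustment

Low-ctDNA (MSAF < 1%) patients respond better in unadjusted
comparisons, but they also carry favourable baseline prognostics. The
adjustment pipeline screens baseline factors at P < 0.15 — Wilcoxon
rank-sum for continuous factors, chi-square for categorical with a
Fisher fallback when an expected cell is below 5 (the screening tests
are a documented package choice; only the 0.15 level is externally
given) — fits a logistic propensity model for MSAF < 1% membership on
the selected factors (missing PD-L1 stays as an explicit category), and
reweights each patient by the inverse probability of their own group.
Weights are unstabilised by default with truncation at the 1st/99th
percentiles (stabilised weights by flag); the weighted odds ratio uses
a sandwich (HC0) robust variance, and weighted Kaplan–Meier and Cox
fits give adjusted PFS summaries. Separation is declared only when a
patient's own-group probability vanishes — that is when a weight
diverges; a fitted zero on the other side is a sparse cell, not a
weighting failure. The weighted-median convention is the weighted
product-limit curve's first crossing of 0.5; adjusted medians from
patient-level trial data are not targeted.

## The gene landscape

`gene_prevalence()` works on the raw variant table without germline or
driver filtering — exploratory landscape pipelines keep everything the
caller emitted, so inherited variants and clonal hematopoiesis may
contribute, which is stated rather than hidden. Prevalence is computed
in the molecularly evaluable population (every sample with a variant
table, any MSAF); genes below 2% prevalence there are dropped; retained
genes are tested high vs low among evaluable samples by two-sided
Fisher exact tests with Benjamini–Hochberg adjustment. No gene-size
normalisation and no external-database artifact screening are applied.

## The synthetic trial generator

Patient-level data from such trials are access-controlled, so the
package ships a generator whose defaults are the published cohort
anchors, and all validation runs against it:

* 152 patients; evaluability drawn at 78%; the evaluable score
  distribution is a discretised log-normal (sdlog 0.8, a typical spread
  for mutation counts) quantile-matched so P(score ≥ 16) = 24%. The
  two anchor fractions are the only published calibration targets; the
  true per-patient score distribution is not public.
* Each patient's variant profile is constructed so that scoring it
  reproduces the intended truth exactly: exactly `score` qualifying
  substitutions with AF in [0.5%, MSAF], one call anchoring the MSAF,
  plus decoys the filters must remove — germline variants near 0.5/1.0
  AF (85% database-flagged, the rest caught by the band rule), known
  drivers, indels, sub-threshold calls, and database-flagged low-AF
  calls. Gene assignment is weighted toward recurrently mutated
  lung-cancer genes so landscape analyses see familiar enrichment.
* Response probabilities (35.7% high / 5.5% low / 37.9% non-evaluable)
  and exponential PFS/OS medians (5 / 3.5 / 6.8 months PFS, 23.9 /
  13.4 / 20 months OS) follow the published group summaries; censoring
  is administrative, uniform over 0.5–31.4 months of follow-up.
  Exponential hazards are the default for analytic tractability of the
  recovery tests.
* Baseline covariates carry the published MSAF-subgroup shifts (age,
  current smoking, PD-L1 positivity with 36% missingness, lesion count,
  tumor size).
* For the cutoff-sweep validation, an optional log-linear score effect
  replaces the group model: hazard ∝ exp(θ·(score − 10)). θ = −0.12 per
  mutation was calibrated once so the large-cohort high-vs-low hazard
  ratio declines across cutoffs 10→20 by the published gradient (a log
  ratio near −0.75); it is a planted-trend condition, not an estimate.
* `simulate_confounded_msaf()` plants the structure the IPW module must
  undo: a favourable-prognosis index (younger age, smaller tumors,
  fewer lesions, non-smoking, PD-L1-positive) raises both the
  probability of MSAF < 1% membership (logistic coefficient 1.2,
  intercept set for ~20% prevalence) and the probability of response;
  MSAF has no causal effect. Setting `confound_strength = 0` removes
  the planted effects.

Identical configuration and seed reproduce a trial byte for byte.

**What passing tests show — and do not.** The generator produces clean
exponential outcomes, exact score round trips and correctly specified
propensity models. Validation against it establishes that the
implementations are correct (estimators match independent oracles,
planted parameters are recovered, intervals achieve nominal coverage),
not that the assay or the adjustment would behave identically on real
plasma data, where read-level noise, clonal hematopoiesis, model
misspecification and informative censoring all exist. Published
survival medians and hazard ratios that depend on the access-controlled
patient-level data are deliberately not targeted.

## Validation scale

The test suite validates at these sizes, chosen to make Monte-Carlo
error small relative to the tolerances: Cox recovery of a planted HR
0.6 with 150 patients per arm over 500 replicates (mean log-HR bias
within ±0.05); Brookmeyer–Crowley and Greenwood coverage on 1,000
exponential cohorts of 200 (nominal ±3 points); Blaker-inside-
Clopper–Pearson for every x ≤ n ≤ 60; IPW confounder removal over 500
replicates (adjusted interval covering the null in ≥ 90%); sweep trend
recovery over 200 replicates (negative Spearman correlation in ≥ 90%);
scoring against a brute-force oracle on 1,000 random fixtures; and
calibration of the two cohort anchors over 500 replicates (±3 points).
`scripts/acceptance.R` recomputes the same quantities end to end and
writes them as JSON.

## Known limitations

* The germline band rule is a surrogate; real zygosity classifiers use
  read depth and purity, so band misclassification on real data is
  unmodelled.
* Copy-number alterations, read-level simulation and sequencing error
  are out of scope; variant calls are taken as given.
* The Cox implementation handles a single binary covariate — all the
  trial's stratified analyses need — not multivariable models.
* Exact permutation log-rank is exhaustive only; it refuses rather than
  subsamples beyond its enumeration cap.
* Efficacy endpoints are deliberately unadjusted for multiplicity,
  matching the descriptive reporting convention of the design.
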