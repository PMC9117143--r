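# btmbtools

Blood tumor mutational burden (bTMB) scoring and biomarker-stratified
trial analysis in R.

## The problem

In advanced non-small cell lung cancer, tumor mutational burden measured
from plasma cell-free DNA (bTMB) is a candidate predictive biomarker for
checkpoint-inhibitor benefit when tissue is unavailable. A bTMB assay
counts somatic single-nucleotide substitutions over a fixed hybrid-capture
panel (394 genes, 1.1 Mb of coding sequence) after removing germline
variants and known drivers; a score of 16 corresponds to ~14.5 mutations
per megabase. The assay only works when enough circulating tumor DNA is
present, gated by the maximum somatic allele frequency (MSAF ≥ 1%).

`btmbtools` implements the full computational chain of a single-arm,
biomarker-stratified phase 2 analysis of such an assay, for
biostatisticians who want a tested, reusable, open implementation:

* **Scoring** (`classify_germline()`, `compute_msaf()`, `compute_btmb()`,
  `classify_btmb_group()`): MSAF estimation, evaluability gating,
  germline filtering (population-database membership plus an allele-
  frequency band surrogate for somatic-germline-zygosity classification),
  driver removal, substitution counting, mut/Mb conversion.
* **Efficacy statistics**, written from first principles:
  Blaker exact binomial intervals (`blaker_ci()`), Cochran–Mantel–Haenszel
  tests (`cmh_test()`), Wald rate differences, Woolf odds ratios,
  Kaplan–Meier curves with Greenwood variance (`km_fit()`),
  Brookmeyer–Crowley median intervals (`km_median_ci()`), log-rank tests
  with an exact permutation option (`logrank_test()`), Cox hazard ratios
  with Efron tie handling and optional case weights (`cox_hr()`), and
  Schoenfeld log-rank power (`logrank_power()`).
* **Cutoff sweep** (`btmb_cutoff_sweep()`): the secondary analysis over
  score cutoffs 10–20 by 2.
* **IPW adjustment** (`screen_factors()`, `fit_propensity()`,
  `ipw_estimate()`): propensity-score inverse-probability weighting of
  the low-ctDNA (MSAF < 1%) subgroup comparison after a P < 0.15 factor
  screen.
* **Gene landscape** (`gene_prevalence()`): per-gene alteration
  prevalence and Fisher/Benjamini–Hochberg association with bTMB-high
  status.
* **Synthetic trials** (`sim_config()`, `simulate_cohort()`,
  `simulate_confounded_msaf()`): a generator calibrated to the published
  cohort anchors (78% evaluable, 24% bTMB ≥ 16) that emits clinical
  tables and ctDNA variant profiles, so every analysis runs end to end
  with no access-controlled patient data.

Everything takes and returns tibbles, chains with the pipe, and fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(btmbtools)
library(dplyr)

# a complete synthetic trial: clinical table + ctDNA variant calls
sim <- simulate_cohort(sim_config(seed = 7))

# score every sample from its variant calls
scored <- sim$variants |>
  classify_germline() |>
  compute_btmb(sim$panel, sample_ids = sim$clinical$id) |>
  classify_btmb_group(cutoff = 16)

count(scored, btmb_group)
#> # A tibble: 3 × 2
#>   btmb_group        n
#>   <fct>         <int>
#> 1 high             26
#> 2 low              93
#> 3 non_evaluable    33

# the trial-style primary endpoint on the reconstructed published counts
orr_blaker(26, 152) |> select(orr_pct, conf_low_pct, conf_high_pct)
#> # A tibble: 1 × 3
#>   orr_pct conf_low_pct conf_high_pct
#>     <dbl>        <dbl>         <dbl>
#> 1    17.1         11.6          23.9

# biomarker-stratified survival on the synthetic cohort
cl <- sim$clinical |> left_join(scored, by = c(id = "sample_id"))
grp <- cl |> filter(evaluable) |>
  mutate(grp = factor(if_else(btmb_score >= 16, "high", "low"),
                      c("low", "high")))
cox_hr(grp, pfs_time, pfs_event, grp, conf = 0.90)
#> <btmb_cox> HR = 0.890 (90% CI 0.595, 1.332), Wald p = 0.635,
#>   102 events / 119 patients

# the full cutoff sweep (ORR, rate differences, PFS/OS HRs, medians)
sweep <- btmb_cutoff_sweep(cl)
autoplot(sweep)
```

The response rate line reads: 17.1% of the 152 patients had a confirmed
response, with a Blaker exact 95% interval of 11.6–23.9%. The Cox line
estimates the biomarker-high vs low PFS hazard ratio on this synthetic
draw (HR < 1 favours the high group) with its 90% Wald interval; on this
seed the point estimate favours the high group but the interval spans 1,
as one expects from a single 119-patient draw of a moderate planted
effect.

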