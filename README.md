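# walkmem

Analysis pipeline for old/new recognition experiments in which items are
encoded while **physically walking** a tracked virtual environment — two
museum-like rooms whose walls hold nine paintings each, explored along an
instructed route under 10 Hz position/heading tracking, followed by a
77-trial recognition task.

The package is written for behavioural/cognitive researchers who want to
ask how **spatiotemporal encoding context** shapes recognition:

* **Spatial boundary effect** — for consecutive probes of two old items
  where the first was correctly recognised, is the second recognised more
  often when both items were encoded in the *same* room?
* **Ordinal proximity (temporal contiguity) effect** — among same-room
  sequential probes, is recognition better for items encoded at close
  ordinal lag (|lag| ≤ 3) than remote lag (|lag| ≥ 4)?
* **Travelled-distance effect** — does recognition of the second item
  decline with the spatial (m) or temporal (s) distance *physically
  travelled* between the two items during encoding?

The last question is answered with the **distance-based mnemonic
probability function (d-MPF)**: per participant, the hit rate of the
second item of eligible sequential pairs (same room, first item hit),
binned into five equal-width bins of travelled distance pooled over the
cohort. The group-level statistic reduces each participant's d-MPF to a
far-minus-near contrast (or a linear trend across bins) and tests it with
a **sign-flip permutation t-test**:

> T = mean(c) / (sd(c)/√n), with the null distribution from 2,000 random
> sign assignments of the within-participant contrasts c, and
> p_perm = (1 + #{|T*| ≥ |T_obs|}) / (2,001), two-tailed.

Around that core the package provides the conventional battery
(conditional hit rates, source attribution vs. chance .5, per-room HR /
FAR / d′ with 1/(2N) correction, confidence summaries), self-contained
**JZS Bayes factors** (Cauchy prior, scale √2/2, by numerical
integration), exact **noncentral-t paired power**, and a **generative
synthetic-cohort simulator** with injectable `beta_room`, `beta_lag` and
`beta_dist` effects so every stage is testable with ground truth and no
downloads.

## Worked example

Simulate a 30-participant cohort under the default study conditions and
run the full analysis in memory:

```r
library(walkmem)

params <- cohort_params(n_participants = 30, seed = 42)
cohort <- generate_cohort(params)
an     <- analyze_cohort(cohort, analysis_config(), seed = 1)

an$contrasts[, c("statistic", "n", "t", "df", "p", "cohen_d", "bf01")]
#>           statistic  n      t df        p cohen_d    bf01
#>   hr_same_vs_across 30  4.999 29 2.55e-05  0.9126 0.00111
#>  hr_close_vs_remote 29  4.126 28 2.99e-04  0.7662 0.01024
#>    hr_light_vs_dark 30  0.659 29 5.15e-01  0.1204 4.21030
#>   far_light_vs_dark 30 -0.128 29 8.99e-01 -0.0234 5.10545
#> ... (12 contrasts in total)

an$perm_spatial
#> <d-MPF permutation t-test (spatial, extreme_bins): T[13] = -3.38,
#>  p_perm = 0.007496, Cohen's d = -0.90, 14 participants, 2000 permutations>
an$perm_temporal
#> <d-MPF permutation t-test (temporal, extreme_bins): T[13] = -3.50,
#>  p_perm = 0.008996, Cohen's d = -0.94, 14 participants, 2000 permutations>
```

Reading the output: the cohort was generated with a +.07 same-room boost
and a +.13 close-lag boost, and both recover as significant paired
contrasts (mean conditional HR .79 same vs .60 across; .88 close vs .64
remote). The injected −0.03/m distance slope produces declining d-MPFs and
a significantly negative permutation T for both distance metrics; the df
of 13 (from 30 participants) reflects the listwise exclusion of
participants with an empty extreme distance bin. Contrasts with no injected
effect (e.g. HR light vs dark) are non-significant with BF01 > 4 — moderate
evidence for the null. Spatial and temporal distances are nearly collinear
(pooled r = 0.97), so the two d-MPFs agree.

The same pipeline runs file-based, writing every artifact (logs, trials,
responses, visits, distance matrices, participant statistics, contrast
tables, d-MPF tables, permutation JSON, a bar plot and a text report):

```r
outdir <- "scratch/demo"
pipeline_simulate(params, analysis_config(), outdir)
pipeline_features(params, analysis_config(), outdir)
pipeline_analyze (params, analysis_config(), outdir)
pipeline_dmpf    (params, analysis_config(), outdir, seed = 1)
pipeline_report  (params, analysis_config(), outdir)
```

Real sessions are analysed the same way once the trajectory logs are in
the documented CSV dialect (`<participant>_<room>.csv` with header
`t_s,x_m,y_m,heading_deg`) and responses in the documented tidy tables.

## Package layout

| module | contents |
|---|---|
| `R/tracklog.R` | trajectory log format: read, validate, repair, write |
| `R/layout.R`, `R/walk.R` | room layouts, routes, and the walking simulator |
| `R/features.R` | gaze attribution, visits, travelled-distance matrices |
| `R/taskgen.R` | 77-trial sequence, pair-enriching reorder, pair labels |
| `R/recognition.R` | conditional HRs, SDT, source, confidence, contrasts |
| `R/dmpf.R` | d-MPF computation, permutation test, plot |
| `R/stats_core.R` | t-tests, Cohen's d, JZS BF01, noncentral-t power |
| `R/cohort.R`, `R/pipeline.R` | generative cohorts and orchestration |

See `vignettes/walkmem-methods.Rmd` for the models, assumptions, numerical
choices and limitations.
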