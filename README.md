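# hdweight

Personalized dry-weight supervision for hemodialysis patients, from routine
electronic-health-record session logs.

## The problem

End-stage renal disease patients on maintenance hemodialysis (HD) are
prescribed a *dry weight* (DW) — the lowest tolerated post-dialysis weight
with minimal signs of hypo- or hypervolemia. Misjudging DW drives
cardiovascular complications, so clinicians track each patient's
post-dialysis weight session by session and adjust the ultrafiltration (UF)
prescription by trial and error. `hdweight` automates that supervision: it
learns a *personalized* one-session-ahead forecast of the post-dialysis
weight from the patient's own session history (pre-/post-dialysis weights
and UF volumes only — no blood pressure, no lab values), and flags sessions
whose observed weight deviates from the forecast beyond the clinical rule
of thumb (0.5 kg absolute or 1% relative). It is aimed at dialysis-unit
informatics teams and clinical-ML researchers working with longitudinal HD
records.

## The model

The post-dialysis weight series `w_post(t)` is first detrended with an
exponential moving average over the `n` strictly prior sessions,

    EMA_t = sum_{i=1..n} alpha_i * w_post(t - i),      alpha_i ∝ rho^i,
    rho = (n - 1)/(n + 1),
    EMD_t = w_post(t) - EMA_t,

where EMD (the *EMA difference*) is approximately stationary. EMD is then
modeled in two stages on the z-scored feature vector
`F_t = (w_pre(t), w_pre(t-1..t-k), w_post(t-1..t-k), u(t-1..t-k))`
(`3k + 1 = 16` features at the default `k = 5`, about two weeks of history
at 2–3 sessions/week):

1. **Global baseline** — ordinary least squares:
   `EMD_base(x) = b0 + lambda' x`.
2. **Local correction** — Gaussian-kernel locally weighted regression of
   the baseline residuals: training row `j` gets weight
   `w_j = exp(-||x_j - x||^2 / (2 tau^2))`, and
   `EMD_pred = EMD_base + EMD_delta`.

The forecast is reconstructed as `w_post_pred(t) = EMA_t + EMD_pred(t)`,
where `EMA_t` is known at prediction time. Models are strictly per-patient
(no pooling across patients, hence no crowd bias), and evaluation is
rolling-origin: for every target session the full pipeline — missing-weight
imputation via the average weight draft
`delta = mean(w_pre - w_post - u/1000)`, 10%-per-side trimming of extreme
intradialytic weight differences, normalization and both regression
stages — is refit on the sessions strictly before the target.

Prediction errors are calibrated with a maximum-likelihood gamma fit
(location 0) whose CDF at 0.5 kg / 1% summarizes clinical accuracy, and
cohorts are compared with one-way ANOVA plus Holm-adjusted t-tests.

## Worked example

A built-in simulator generates HD cohorts in three clinical flavors
(HD-stabilized, HD-intolerant, near-death) with increasing noise,
dry-weight drift and regime shocks:

```r
library(hdweight)

cohort <- c(simulate_cohort("stabilized", 3, 100, seed = 7),
            simulate_cohort("intolerant", 3, 100, seed = 7),
            simulate_cohort("near_death", 3, 100, seed = 7))
rep <- cohort_report(cohort)   # rolling-origin evaluation, all patients
```

This prints (per pooled group; CDF@0.5kg is the fitted-gamma probability of
an absolute error at or below 0.5 kg, CDF@1% the same for relative error):

```
stabilized  MAE 0.220 kg  MAPE 0.340%  CDF@0.5kg 0.907  CDF@1% 0.957
intolerant  MAE 0.346 kg  MAPE 0.524%  CDF@0.5kg 0.765  CDF@1% 0.857
near_death  MAE 0.644 kg  MAPE 1.110%  CDF@0.5kg 0.521  CDF@1% 0.580
ANOVA on per-patient MAE: F = 22.45, p = 0.001637  (reference: stabilized)
      method    t_stat     p_raw     p_holm reject
1 intolerant -2.458544 0.1023804 0.10238040  FALSE
2 near_death -6.653192 0.0133406 0.02668119   TRUE
```

Accuracy degrades with deteriorating clinical condition — the stabilized
group is predicted within 0.5 kg over 90% of the time, while near-death
patients' chaotic weight behavior breaks the learned regularity. That gap
is the supervision signal: a stable patient drifting away from their own
forecast warrants review.

Single-patient workflow:

```r
ps  <- simulate_cohort("stabilized", 1, 150, seed = 42)[[1]]
res <- rolling_evaluate(ps)                 # k = 5, n = 5, tau = 1, warmup 30
metric_quad(res$post_actual, res$post_pred)
#> MAE 0.2128 kg  MAPE 0.4538%  MSE 0.0766 kg^2  r2 -0.7273
error_cdf(res$abs_error, threshold = 0.5)
#> gamma(shape 1.112, scale 0.1914), n=120: P(err <= 0.5) = 0.9108
nrow(deviation_alert(res))                  # 0.5 kg / 1% OR rule
#> [1] 9
```

(The negative `r2` is expected for a very stable patient: their
post-dialysis weight barely moves, so the per-patient mean is already an
excellent predictor; MAE and the gamma CDF are the clinically meaningful
scores.)

## Command line

```sh
Rscript inst/cli/hdweight.R simulate --group all --patients 5 --seed 7 -o cohort.csv
Rscript inst/cli/hdweight.R evaluate cohort.csv -o report.json
Rscript inst/cli/hdweight.R sweep-k cohort.csv --k 1:10 -o sweep.csv
Rscript inst/cli/hdweight.R report cohort.csv -o results   # results.{json,csv}
```

CSV schema: `patient_id,date,pre_weight_kg,post_weight_kg,uf_ml[,group]`,
ISO-8601 dates, empty field = missing weight.

## Scope

Competing forecasters (ARIMA, random forests, LSTM) are *not* bundled; the
evaluation and comparison harness accepts any predictor's per-patient metric
vectors via `holm_ttests()` / `anova_oneway()`. Blood-pressure variables,
demographic tables and physiological fluid-compartment modeling are out of
scope. See `vignettes/dry-weight-model.Rmd` for the full methods account.
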