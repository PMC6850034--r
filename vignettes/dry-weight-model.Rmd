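---
title: "Personalized dry-weight supervision: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized dry-weight supervision: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdweight)
```

## 1. The estimation problem

A hemodialysis (HD) patient's *dry weight* — the lowest tolerated
post-dialysis weight — is a latent, slowly moving clinical target. The
observable proxy is the trial-and-error post-dialysis weight recorded at
every session by the dialysis machine, together with the pre-dialysis
weight and the prescribed ultrafiltration (UF) volume. `hdweight` treats
dry-weight supervision as one-session-ahead forecasting of the
post-dialysis weight from each patient's own record, with deviations
beyond a clinical threshold (0.5 kg absolute, 1% relative) flagged for
review. Everything is strictly per patient: weight dynamics are highly
individual, and pooling across patients would import crowd bias into a
personal prescription.

## 2. Preprocessing

**Missing weights.** Real HD logs occasionally miss one of the two
weights. Sessions missing *both* are discarded. Otherwise the missing one
is reconstructed through the session mass balance: the *average weight
draft* `delta = mean(w_pre - w_post - u/1000)` (kg; `u` in mL) captures the
systematic gap between UF and actual weight loss — end-of-session saline
return makes it positive for most patients, residual kidney excretion can
make it negative. A missing pre-weight becomes `w_post + u/1000 + delta`.
Only the pre-weight form of this rule is canonical; we impute a missing
post-weight by its algebraic inversion `w_pre - u/1000 - delta`, the unique
consistent reading. Two further choices:

* `delta` is computed from **complete sessions only**, before any
  imputation, so imputed values never feed back into the statistic
  (avoiding a circularity the defining equation does not address);
* imputation is per patient, like everything else.

Re-applying the imputation equation to an imputed session reproduces the
stored value bitwise; the test suite asserts this exactly, not to a
tolerance.

**Outlier trimming.** Sessions with extreme intradialytic weight
differences `w_pre - w_post` (interrupted sessions, transcription errors)
are removed from the *training* data at a rate of 10% per side
(`floor(rate * m)` from each extreme, stable sort so ties keep temporal
order). Two readings of "remove" exist, and they differ materially:

* `trim_outliers()` implements the literal series-level operation — the
  flagged sessions are deleted and the survivors re-indexed;
* inside `fit_emd_model()` trimming removes training **rows** (a feature
  vector/target pair) whose *target* session is flagged, while feature
  histories and EMA windows are still built on the intact series.

We made the second form the fitting behavior because deleting a session
from the middle of a series would silently corrupt the lag structure of
every feature vector built across the gap — the `k` "most recent" sessions
would no longer be the physiologically recent ones. Evaluation targets are
never trimmed. Whether trimming should be per patient or pooled is not
dictated by the method; per patient is the only choice consistent with
personalized models.

**Features and scaling.** The predictors for target session `t` are the
current pre-dialysis weight plus the `k` most recent prior pre-weights,
post-weights and UF volumes — `3k + 1` features, 16 at the default
`k = 5`. Histories are most-recent-first. All features are z-scored with
statistics fitted on the training rows only (never on the query — no
leakage); we fix the **population** (divide-by-m) standard deviation so
that documented tests can assert exact values. Columns that are constant in
training (sd < 1e-12) map to 0 rather than dividing by zero.

## 3. The two-stage EMD model

**Detrending.** The post-dialysis weight series is detrended with an
exponential moving average over the `n` *strictly prior* sessions,
`EMD_t = w_post(t) - EMA(w_post(t-1), ..., w_post(t-n))`. Excluding the
target session from its own EMA is forced by the use case: at prediction
time the current post-weight is unknown, and the reconstruction
`w_post_pred = EMA + EMD_pred` only works if the EMA is a known quantity.
EMD is approximately stationary, which is what makes a small linear model
adequate.

**EMA weights.** With decay ratio `rho = (n-1)/(n+1)`, the package ships
two weight conventions. The piecewise *literal* form (`alpha_1 = rho`,
`alpha_i = rho^i / (1 + S)` for `i > 1`, `S = sum_{j=1..n} rho^j`, the sum
read as constant over `i`) does not sum to 1, so its "average" of a
constant series is biased low. The *normalized* form
(`alpha_i = rho^i / S`, a proper convex combination) is the default: an EMA
that tracks a constant weight exactly is the only behavior consistent with
using it as the reconstruction baseline. The literal mode is retained for
fidelity. The window `n` is conceptually distinct from the feature depth
`k`; both default to 5 and are independently configurable.

**Stage 1 — global baseline.** Ordinary least squares of the EMD targets
on the normalized features (with intercept). Least squares throughout the
package is solved by minimum-norm SVD with relative tolerance `1e-10` on
the singular values, so rank-deficient designs (constant UF prescriptions,
collinear pre/post histories) degrade gracefully instead of crashing; a
warning is logged on direct fits and suppressed inside the rolling
protocol, where collinearity is routine.

**Stage 2 — Gaussian-kernel local correction.** The baseline's residuals
carry local, nonlinear structure. The default `sample_weight` mode gives
every training row the kernel weight
`w_j = exp(-||x_j - x||^2 / (2 tau^2))` in *normalized* feature space and
refits the residuals by weighted least squares, evaluated at the query;
`EMD_pred = EMD_base + EMD_delta`. Two sign/form decisions were genuinely
open:

* The correction models **residuals** (`EMD - EMD_base`), so that
  `EMD_base + EMD_delta` approximates EMD — the only internally consistent
  reading — and so that `tau -> Inf` collapses the two stages exactly onto
  one-stage global least squares (asserted at `tau = 1e9` to `1e-6`).
* An `elementwise` mode is kept in which each design entry is scaled by a
  per-feature kernel factor before an unweighted refit — the literal
  transcription of the kernel formula applied to feature values — but the
  default is the sample-weight form, which is standard locally weighted
  regression and matches the intuition of "weighting nearby training
  points".

**Bandwidth and degeneracy.** `tau` has no canonical published value; the
default is `tau = 1.0` in normalized-feature units (one training-set
standard deviation per coordinate), configurable everywhere. In 16
dimensions a unit bandwidth is conservative: typical inter-point distances
make most kernel weights tiny, so the correction only activates when the
record contains genuinely close precedents. When the effective sample size
`sum(w_j)` drops below the feature count + 1 a weighted fit would be
ill-posed, and the correction falls back to 0 with a warning (suppressed in
rolling runs). This keeps the estimator conservative exactly where locality
has no support.

## 4. Evaluation protocol

The original train/test split for per-patient records is not specified
anywhere; we adopt **rolling-origin** evaluation as the package's protocol
and flag it as such: for each target `t` from `warmup` (default 30) to the
end, imputation statistics, trimming, normalization and both regression
stages are refit on sessions strictly before `t`. The no-leakage contract
is bit-level — perturbing any session after `t` leaves the prediction at
`t` identical — and is tested as such. A warmup of 30 leaves at least
`3k + 2` training rows at the defaults and equals roughly ten weeks of
history at 2–3 sessions/week.

**Metrics.** MAE (kg), MSE (kg²) and `r² = 1 - SSE/SST` are computed on
(actual, predicted) post-weight pairs. For MAPE the literal detrended form
would divide by the EMD value itself — numerically explosive since EMD
crosses zero, and inconsistent with reported magnitudes of relative error
in this field, which divide by the patient's post-dialysis weight. The
default therefore divides by the actual post-weight (so MAPE ≈ MAE/weight
× 100); the EMD-denominator form remains available via the `denominators`
argument. `r²` on a near-constant stable patient is legitimately small or
negative (the patient mean is already a fine predictor); MAE and the error
CDF carry the clinical meaning there.

**Error calibration.** Absolute and relative errors are nonnegative, so
they are calibrated with a gamma fit, location pinned at 0, by maximum
likelihood (Newton on the shape equation
`log(shape) - digamma(shape) = log(mean x) - mean(log x)`); exact zeros
are clipped to `1e-6` to keep the likelihood finite. The reported quantity
is the fitted CDF at the clinical thresholds (0.5 kg, 1%). Group CDFs are
fitted on errors **pooled per group** (rather than averaged per patient):
the pooled distribution is what a unit-level alarm actually samples from.

**Comparisons.** One-way ANOVA on per-patient metric values across groups
or methods, then Holm step-down t-tests. Method comparisons on the same
patients are **paired** (each patient contributes one value per method);
group comparisons are unpaired (different patients). The pairing choice is
ours — it is the higher-powered and more defensible design when samples
share patients, but is configurable.

## 5. The synthetic cohort generator

There is no deposited clinical dataset, so the test bed is a seeded
simulator (`simulate_patient()` / `simulate_cohort()`) stating the world
the model assumes: per session, dry weight `DW_t` follows
drift + random walk (+ shocks); interdialytic gain is drawn
`N(gain_mean, gain_sd)` truncated at 0; `pre_t = post_{t-1} + gain_t`; the
UF prescription targets the dry weight, `uf_t = max(0, pre_t - DW_t)`
(converted to mL); and
`post_t = pre_t - uf_t/1000 + saline_t + N(0, post_noise_sd)` with the
saline return truncated at 0 — so UF systematically exceeds the weight
difference, reproducing the qualitative mass-balance pattern of real
records, and the noise-free configuration has the exact fixed point
`post ≡ dw0`. Truncation is implemented as clipping at zero; at the default
means/SDs the clipped mass is below 2.5% and nothing downstream depends on
the distinction. Dates follow a Mon/Wed/Fri pattern (2–3 sessions/week);
the model itself ignores calendar gaps and treats sessions as an ordered
sequence.

Defaults (all overridable): `dw0 = 60` kg (cohorts draw U(45, 85)),
`gain_mean = 2.5` kg, `gain_sd = 0.5` kg — a typical interdialytic gain —
and saline return `0.2 ± 0.1` kg, a plausible end-of-session flush; the
saline magnitude is a documented placeholder, chosen once, since only the
qualitative pattern (UF above weight loss) is established. Group presets
encode the clinical difficulty ordering:

| preset | drift (kg/session) | RW sd | post noise sd | shock prob / sd |
|---|---|---|---|---|
| stabilized | 0 | 0.02 | 0.15 | 0 / – |
| intolerant | 0 | 0.05 | 0.30 | 0.05 / 0.5 |
| near_death | −0.03 | 0.08 | 0.45 | 0.15 / 1.0 |

Missingness (`inject_missing()`) hits pre *or* post (never both, a fair
coin), independently per session; UF is never missing, consistent with
machine auto-capture. All randomness flows from explicit seeds through a
fixed generator (Mersenne-Twister, inversion normals), with per-patient
substreams derived deterministically, so cohorts are reproducible across
platforms and the caller's RNG state is never disturbed.

A separate statistical test bed, `simulate_linear_emd_patient()`, is *not*
physiologic: UF is exogenous noise and each post-weight is constructed as
`EMA + (linear function of the UF history) + N(0, sigma)`, so the EMD
target is exactly linear in the features. It exists to make two properties
checkable: with `sigma = 0` the pipeline must recover every weight to
machine precision, and with `sigma > 0` the rolling MAE must approach the
folded-normal floor `sigma * sqrt(2/pi)` (the suite requires the 20-seed
mean within 25%, absorbing finite-sample estimation inflation).

**What a green suite does and does not establish.** It establishes
algorithmic correctness (oracle equivalence of every numerical component),
the no-leakage protocol, exact recovery in the noise-free world, correct
noise-floor behavior, and that the difficulty ordering across simulated
clinical groups emerges from the model rather than being asserted. It does
**not** establish clinical accuracy on real patients: the simulator has no
intercurrent illnesses, medication changes, nutrition trends, seasonal
effects, or informative missingness, and its parameters are stated rather
than estimated from records.

## 6. Numerical choices, degenerate inputs, limitations

* Weights are validated to (20, 200) kg; violations are errors, not
  warnings — silent pass-through of a 250 kg typo would poison `delta`.
* CSV serialization uses 3 decimals (gram resolution); round-trips are
  exact at that resolution, and missing weights are empty fields, never 0.
* Duplicate (patient, date) rows are an error: the model assumes one
  session per record, and merging would require a policy we refuse to
  invent silently.
* Ties in trimming keep temporal order (stable sort); `floor()` per side.
* `n = 1` EMA windows are rejected (`rho = 0` is a degenerate "decay").
* Constant-actual `r²` is `NaN` with a warning rather than an arbitrary 0.
* All-zero error vectors yield a degenerate gamma fit with CDF 1 and a
  warning; fewer than 10 positive errors are an error.
* Current-session UF (`u_0`) is *not* a feature: the feature definition
  uses only historical UF, and at supervision time the current session's
  final UF may not be closed out.

Known limitations: forecasts are one session ahead only; the model reacts
to, rather than anticipates, regime shocks (visible as the near-death
group's error inflation); `tau` is fixed rather than selected per patient;
and the comparison harness ships no competing forecasters — external
ARIMA/RF/LSTM predictions can be compared by passing their per-patient
metric vectors to `anova_oneway()` / `holm_ttests()`.
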