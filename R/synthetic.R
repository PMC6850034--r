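# run expr under a private RNG stream (Mersenne-Twister), restoring the
# caller's .Random.seed afterwards; all simulator determinism flows from here
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

# deterministic 31-bit sub-seed derivation
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 1000003 + (p %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Simulation configuration for one synthetic hemodialysis patient
#'
#' The generator emulates the statistical structure of a dialysis weight
#' log: a slowly varying dry weight (deterministic drift + random walk +
#' optional regime shocks), interdialytic fluid gain, an ultrafiltration
#' prescription targeting the dry weight, end-of-session saline
#' supplementation (so UF usually exceeds the intradialytic weight loss),
#' measurement noise on the post-dialysis weight, and optional missing
#' weight entries.
#'
#' @param group Clinical flavor: `"stabilized"`, `"intolerant"` or
#'   `"near_death"`.
#' @param n_sessions Number of sessions (default 150, the typical per-patient
#'   record length).
#' @param dw0 Initial dry weight, kg.
#' @param dw_drift Deterministic dry-weight drift, kg/session.
#' @param dw_rw_sd Dry-weight random-walk step SD, kg.
#' @param gain_mean,gain_sd Interdialytic weight gain, kg (truncated at 0).
#' @param saline_mean,saline_sd End-of-session fluid return, kg
#'   (truncated at 0).
#' @param post_noise_sd Post-dialysis weight measurement noise SD, kg.
#' @param shock_prob,shock_sd Per-session probability and SD of a dry-weight
#'   regime shock (clinical instability).
#' @param missing_rate Fraction of sessions losing one weight entry.
#' @param seed RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(group = "stabilized", n_sessions = 150,
                              dw0 = 60, dw_drift = 0, dw_rw_sd = 0.02,
                              gain_mean = 2.5, gain_sd = 0.5,
                              saline_mean = 0.2, saline_sd = 0.1,
                              post_noise_sd = 0.15,
                              shock_prob = 0, shock_sd = 0.8,
                              missing_rate = 0, seed = 1) {
  group <- match.arg(group, c("stabilized", "intolerant", "near_death"))
  cfg <- list(group = group, n_sessions = n_sessions, dw0 = dw0,
              dw_drift = dw_drift, dw_rw_sd = dw_rw_sd,
              gain_mean = gain_mean, gain_sd = gain_sd,
              saline_mean = saline_mean, saline_sd = saline_sd,
              post_noise_sd = post_noise_sd, shock_prob = shock_prob,
              shock_sd = shock_sd, missing_rate = missing_rate, seed = seed)
  if (cfg$n_sessions < 1) stop("n_sessions must be >= 1")
  sds <- c(cfg$dw_rw_sd, cfg$gain_sd, cfg$saline_sd, cfg$post_noise_sd,
           cfg$shock_sd)
  if (any(sds < 0)) stop("standard deviations must be nonnegative")
  if (cfg$shock_prob < 0 || cfg$shock_prob > 1)
    stop("shock_prob must be in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$dw0 <= 20 || cfg$dw0 >= 200) stop("dw0 must lie in (20, 200) kg")
  structure(cfg, class = "simulation_config")
}

# Mon/Wed/Fri calendar: 3 sessions a week starting on a Monday
session_dates <- function(n, start = as.Date("2018-01-01")) {
  week <- (seq_len(n) - 1) %/% 3
  dow <- c(0, 2, 4)[(seq_len(n) - 1) %% 3 + 1]
  start + 7 * week + dow
}

#' Simulate one synthetic hemodialysis patient
#'
#' Generative recursion per session `t` (all draws seeded):
#' `DW_t = DW_{t-1} + drift + N(0, dw_rw_sd) [+ shock]`;
#' `pre_t = post_{t-1} + gain_t` with `gain_t ~ N(gain_mean, gain_sd)`
#' truncated at 0; prescribed `uf_t = max(0, pre_t - DW_t) * 1000` mL;
#' `post_t = pre_t - uf_t/1000 + saline_t + N(0, post_noise_sd)` with
#' `saline_t ~ N(saline_mean, saline_sd)` truncated at 0. With all noise
#' terms, drift and saline at 0 the recursion has the exact fixed point
#' `post_t = dw0`. Dates follow a Mon/Wed/Fri pattern.
#'
#' @param config A [simulation_config()].
#' @param patient_id Identifier for the generated series.
#' @return A [patient_series()] carrying the config's group label.
#' @export
simulate_patient <- function(config, patient_id = "sim1") {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_sessions
  with_seed(config$seed, {
    dw <- config$dw0
    prev_post <- config$dw0
    pre <- post <- uf <- numeric(n)
    for (t in seq_len(n)) {
      dw <- dw + config$dw_drift + stats::rnorm(1, 0, config$dw_rw_sd)
      if (config$shock_prob > 0 &&
          stats::runif(1) < config$shock_prob)
        dw <- dw + stats::rnorm(1, 0, config$shock_sd)
      gain <- max(0, stats::rnorm(1, config$gain_mean, config$gain_sd))
      pre[t] <- prev_post + gain
      uf[t] <- max(0, pre[t] - dw) * 1000
      saline <- max(0, stats::rnorm(1, config$saline_mean, config$saline_sd))
      post[t] <- pre[t] - uf[t] / 1000 + saline +
        stats::rnorm(1, 0, config$post_noise_sd)
      prev_post <- post[t]
    }
    ps <- patient_series(patient_id, session_dates(n), pre, post, uf,
                         group = config$group)
    if (config$missing_rate > 0)
      ps <- inject_missing(ps, config$missing_rate,
                           seed = derive_seed(config$seed, 77))
    ps
  })
}

# group presets: noise/instability ordered stabilized < intolerant < near_death
.hdw_presets <- list(
  stabilized = list(dw_drift = 0, dw_rw_sd = 0.02, post_noise_sd = 0.15,
                    shock_prob = 0, shock_sd = 0.8),
  intolerant = list(dw_drift = 0, dw_rw_sd = 0.05, post_noise_sd = 0.30,
                    shock_prob = 0.05, shock_sd = 0.5),
  near_death = list(dw_drift = -0.03, dw_rw_sd = 0.08, post_noise_sd = 0.45,
                    shock_prob = 0.15, shock_sd = 1.0)
)

#' Simulate a cohort of synthetic patients from a clinical-group preset
#'
#' Presets encode the expected difficulty ordering of the three clinical
#' groups (stabilized < intolerant < near-death in noise, instability and
#' dry-weight shocks). Each patient receives a deterministic sub-seed
#' derived from `seed`, the group and the patient number, plus an initial
#' dry weight drawn from U(45, 85) kg.
#'
#' @param group `"stabilized"`, `"intolerant"` or `"near_death"`.
#' @param n_patients Number of patients.
#' @param n_sessions Sessions per patient (default 150).
#' @param seed Cohort seed.
#' @param missing_rate Per-session missing-weight rate (default 0).
#' @return A named list of [patient_series()].
#' @export
#' @examples
#' cohort <- simulate_cohort("stabilized", n_patients = 2, n_sessions = 60,
#'                           seed = 7)
#' names(cohort)
simulate_cohort <- function(group, n_patients, n_sessions = 150, seed = 1,
                            missing_rate = 0) {
  if (!group %in% names(.hdw_presets)) stop("unknown group: ", group)
  preset <- .hdw_presets[[group]]
  gcode <- match(group, names(.hdw_presets))
  out <- list()
  for (i in seq_len(n_patients)) {
    sub <- derive_seed(seed, gcode, i)
    dw0 <- with_seed(derive_seed(sub, 1), stats::runif(1, 45, 85))
    cfg <- do.call(simulation_config,
                   c(list(group = group, n_sessions = n_sessions, dw0 = dw0,
                          missing_rate = missing_rate, seed = sub), preset))
    id <- sprintf("%s_%02d", group, i)
    out[[id]] <- simulate_patient(cfg, patient_id = id)
  }
  out
}

#' Inject missing weight entries into a series
#'
#' Each session independently loses, with probability `rate`, exactly one of
#' its two weights (fair coin); a session never loses both, so no session is
#' silently discarded downstream.
#'
#' @param series A [patient_series()].
#' @param rate Missingness probability per session, in `[0, 1)`.
#' @param seed RNG seed for the mask.
#' @return The series with `NA`s injected.
#' @export
inject_missing <- function(series, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(series)
  s <- series$sessions
  with_seed(seed, {
    hit <- stats::runif(nrow(s)) < rate
    which_pre <- stats::runif(nrow(s)) < 0.5
    s$pre_weight[hit & which_pre] <- NA_real_
    s$post_weight[hit & !which_pre] <- NA_real_
  })
  replace_sessions(series, s)
}

#' Simulate a patient whose EMD is exactly linear in the features
#'
#' A synthetic statistical test-bed (not a physiologic simulation): UF
#' volumes are exogenous `N(uf_mean, uf_sd)` draws and each post-dialysis
#' weight is generated as
#' `post_t = EMA(post_{t-1..t-n}) + sum_j beta_j * (uf_{t-j} - uf_mean)/1000
#'  + N(0, sigma)`,
#' so the detrended EMD target is, by construction, an exact linear function
#' of the `3k + 1` feature vector (coefficients zero outside the UF history)
#' plus i.i.d. Gaussian noise. With `sigma = 0` the model must recover every
#' post-dialysis weight exactly; with `sigma > 0` the best attainable rolling
#' MAE is the folded-normal mean `sigma * sqrt(2/pi)`.
#'
#' @param n_sessions Number of sessions.
#' @param k,n Feature depth and EMA window the generating process uses.
#' @param beta Length-`k` coefficients on the centered UF history (kg per L);
#'   default `c(0.3, -0.1, 0.05, 0, ...)`.
#' @param sigma Noise SD in kg.
#' @param uf_mean,uf_sd Exogenous UF distribution (mL).
#' @param gain_mean Deterministic interdialytic gain used for the
#'   pre-dialysis weights, kg.
#' @param post0 Starting post-dialysis weight, kg.
#' @param ema_mode EMA convention, see [ema_weights()].
#' @param seed RNG seed.
#' @param patient_id Identifier.
#' @return A [patient_series()].
#' @export
simulate_linear_emd_patient <- function(n_sessions = 150, k = 5, n = 5,
                                        beta = NULL, sigma = 0.1,
                                        uf_mean = 2000, uf_sd = 300,
                                        gain_mean = 2.5, post0 = 60,
                                        ema_mode = "normalized", seed = 1,
                                        patient_id = "linear1") {
  if (is.null(beta)) beta <- c(0.3, -0.1, 0.05, rep(0, max(0, k - 3)))[1:k]
  stopifnot(length(beta) == k, sigma >= 0)
  w <- ema_weights(n, ema_mode)
  t0 <- max(k, n)
  with_seed(seed, {
    uf <- pmax(0, stats::rnorm(n_sessions, uf_mean, uf_sd))
    post <- numeric(n_sessions)
    post[seq_len(t0)] <- post0 + stats::rnorm(t0, 0, 0.2)
    for (t in (t0 + 1):n_sessions) {
      e <- ema(post[t - seq_len(n)], w)
      drive <- sum(beta * (uf[t - seq_len(k)] - uf_mean) / 1000)
      post[t] <- e + drive + stats::rnorm(1, 0, sigma)
    }
    gains <- rep(gain_mean, n_sessions)
    pre <- c(post0, post[-n_sessions]) + gains
    patient_series(patient_id, session_dates(n_sessions), pre, post, uf)
  })
}
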