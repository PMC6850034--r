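test_that("ema_weights match both conventions exactly", {
  w2 <- ema_weights(2, "normalized")
  expect_equal(w2$rho, 1 / 3)
  expect_equal(w2$alphas, c(0.75, 0.25))

  # literal reading at n = 5, exact rational oracle:
  # rho = 2/3, S = sum_{j=1..5} rho^j = 422/243, 1 + S = 665/243
  lit <- ema_weights(5, "literal")
  expect_equal(lit$alphas[1], 2 / 3)
  expect_equal(lit$alphas[2], (4 / 9) * (243 / 665))
  expect_equal(lit$alphas[5], (32 / 243) * (243 / 665))

  for (n in c(2, 3, 5, 10, 25)) {
    nw <- ema_weights(n, "normalized")
    expect_equal(sum(nw$alphas), 1)
    expect_true(all(diff(nw$alphas) < 0))
    expect_true(all(nw$alphas > 0))
    lw <- ema_weights(n, "literal")
    expect_true(all(diff(lw$alphas) < 0))
  }
  expect_error(ema_weights(1), "n must be")
})

test_that("ema is the stated dot product", {
  w <- ema_weights(2, "normalized")
  expect_equal(ema(c(60, 62), w), 60.5)
  expect_equal(ema(rep(3.7, 2), w), 3.7)
  expect_error(ema(1:3, w), "length mismatch")

  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    v <- rnorm(n, 60, 3)
    wts <- ema_weights(n, sample(c("normalized", "literal"), 1))
    oracle <- 0
    for (j in seq_len(n)) oracle <- oracle + wts$alphas[j] * v[j]
    expect_equal(ema(v, wts), oracle)
  }
})

test_that("emd_series detrends with the strictly prior EMA", {
  cst <- patient_series("c", as.Date("2020-01-01") + 2 * (0:9),
                        rep(62.5, 10), rep(60, 10), rep(2000, 10))
  ed <- emd_series(cst, 5)
  expect_equal(ed$index, 5:9)
  expect_equal(ed$emd, rep(0, 5))

  step <- cst
  step$sessions$post_weight[8] <- 61   # +1 kg on constant history
  ed2 <- emd_series(step, 5)
  expect_equal(ed2$emd[ed2$index == 7], 1)

  ps <- make_complete_series(20, seed = 5)
  ed3 <- emd_series(ps, 4)
  expect_equal(ed3$ema_value + ed3$emd,
               ps$sessions$post_weight[ed3$index + 1])
  expect_error(emd_series(cst, 10), "too short")
})

test_that("fit recovers exact-linear and null targets", {
  ps <- make_complete_series(60, seed = 7)
  st <- fit_emd_model(ps, k = 3, n = 3, trim_rate = 0)
  # null-target fit: overwrite targets by refitting on a constant-post series
  cst <- patient_series("c", ps$sessions$date, ps$sessions$pre_weight,
                        rep(60, 60), ps$sessions$uf_ml)
  # constant post-weight: degenerate columns are expected and warned about
  expect_warning(st0 <- fit_emd_model(cst, k = 3, n = 3, trim_rate = 0),
                 "rank-deficient")
  expect_true(all(abs(st0$base_coefs) < 1e-10))

  # exact interpolation regime: EMD linear in the features, no noise
  lin <- simulate_linear_emd_patient(80, k = 3, n = 3, sigma = 0, seed = 11,
                                     beta = c(0.3, -0.1, 0.05))
  stl <- suppressWarnings(fit_emd_model(lin, k = 3, n = 3, trim_rate = 0))
  resid <- stl$training_resid
  expect_true(max(abs(resid)) < 1e-8)

  # random well-conditioned instance vs normal-equations oracle
  Xn <- st$training_features
  oracle <- oracle_ls(cbind(1, Xn), st$training_emd)
  expect_equal(unname(st$base_coefs), unname(oracle), tolerance = 1e-8)

  expect_error(fit_emd_model(make_complete_series(12, seed = 1), k = 5, n = 5),
               "too few training rows")
})

test_that("predict_emd: kernel limits, local oracle, null residuals", {
  ps <- make_complete_series(60, seed = 9)
  x <- build_features(ps, 3, 30)

  # tau -> Inf: two-stage equals one-stage global least squares
  sti <- fit_emd_model(ps, k = 3, n = 3, tau = 1e9, trim_rate = 0)
  pr <- predict_emd(sti, x)
  one_stage <- oracle_ls(cbind(1, sti$training_features), sti$training_emd)
  xn <- apply_norm(unclass(x), sti$norm_stats)
  expect_equal(pr$emd_pred, unname(sum(c(1, xn) * one_stage)),
               tolerance = 1e-6)

  # narrow kernel at a training row: matches weighted normal-equations oracle
  stq <- fit_emd_model(ps, k = 3, n = 3, tau = 0.8, trim_rate = 0)
  xq <- build_features(ps, 3, 25)
  xqn <- apply_norm(unclass(xq), stq$norm_stats)
  w <- exp(-rowSums(sweep(stq$training_features, 2, xqn)^2) / (2 * 0.8^2))
  prq <- predict_emd(stq, xq, quiet = TRUE)
  if (sum(w) >= ncol(stq$training_features) + 1) {
    cf <- oracle_ls(cbind(1, stq$training_features), stq$training_resid, w)
    expect_equal(prq$emd_delta, unname(sum(c(1, xqn) * cf)), tolerance = 1e-8)
  } else {
    expect_equal(prq$emd_delta, 0)
  }
  expect_equal(prq$emd_pred, prq$emd_base + prq$emd_delta)

  # residuals identically zero => zero correction
  lin <- simulate_linear_emd_patient(80, k = 3, n = 3, sigma = 0, seed = 3,
                                     beta = c(0.2, 0, 0))
  stl <- suppressWarnings(fit_emd_model(lin, k = 3, n = 3, trim_rate = 0))
  prl <- predict_emd(stl, build_features(lin, 3, 50), quiet = TRUE)
  expect_equal(prl$emd_delta, 0, tolerance = 1e-8)

  expect_error(predict_emd(stq, c(xq[-1], NaN)), "non-finite")
})

test_that("elementwise kernel mode matches its literal oracle", {
  ps <- make_complete_series(50, seed = 13)
  st <- fit_emd_model(ps, k = 2, n = 2, tau = 1.5, trim_rate = 0,
                      kernel_mode = "elementwise")
  x <- build_features(ps, 2, 30)
  xn <- apply_norm(unclass(x), st$norm_stats)
  K <- exp(-sweep(st$training_features, 2, xn)^2 / (2 * 1.5^2))
  cf <- oracle_ls(cbind(1, st$training_features * K), st$training_resid)
  pr <- predict_emd(st, x)
  expect_equal(pr$emd_delta, unname(sum(c(1, xn) * cf)), tolerance = 1e-8)
})

test_that("monotone locality: smaller tau never raises a kernel weight", {
  ps <- make_complete_series(40, seed = 17)
  st <- fit_emd_model(ps, k = 3, n = 3, trim_rate = 0)
  xn <- apply_norm(unclass(build_features(ps, 3, 20)), st$norm_stats)
  d2 <- rowSums(sweep(st$training_features, 2, xn)^2)
  for (tau_pair in list(c(2, 1), c(1, 0.5), c(0.5, 0.05))) {
    w_big <- exp(-d2 / (2 * tau_pair[1]^2))
    w_small <- exp(-d2 / (2 * tau_pair[2]^2))
    expect_true(all(w_small <= w_big + 1e-15))
  }
})

test_that("predict_post reconstructs post weight from EMA + EMD", {
  cst <- patient_series("c", as.Date("2020-01-01") + 2 * (0:39),
                        rep(62.5, 40), rep(60, 40), rep(2000, 40))
  st <- suppressWarnings(fit_emd_model(cst, k = 3, n = 3))
  pp <- predict_post(st, cst, 35, quiet = TRUE)
  expect_equal(pp$post_pred, 60)
  expect_equal(pp$abs_error, 0)

  ps <- make_complete_series(60, seed = 19)
  stp <- fit_emd_model(ps, k = 3, n = 3, trim_rate = 0)
  for (t in c(10, 30, 55)) {
    r <- predict_post(stp, ps, t, quiet = TRUE)
    # reconstruction holds bitwise in the construction order ...
    expect_identical(r$post_pred, r$ema_value + r$emd_pred)
    # ... and the error on post-weights equals the error on EMD
    expect_equal(r$abs_error, abs(r$emd_pred -
                                    (r$post_actual - r$ema_value)))
  }
  expect_error(predict_post(stp, ps, 2), "insufficient history")
})

test_that("rolling_evaluate refits on strict prefixes only", {
  ps <- simulate_patient(simulation_config(n_sessions = 60, seed = 23))
  res <- rolling_evaluate(ps, warmup = 30)
  expect_equal(nrow(res), 30)
  expect_equal(res$target_index, 30:59)

  # no-leakage: perturbing sessions after t leaves prediction at t unchanged
  ps2 <- ps
  ps2$sessions$post_weight[41:60] <- ps2$sessions$post_weight[41:60] + 5
  ps2$sessions$pre_weight[41:60] <- ps2$sessions$pre_weight[41:60] + 5
  res2 <- rolling_evaluate(ps2, warmup = 30)
  expect_identical(res$post_pred[res$target_index < 40],
                   res2$post_pred[res2$target_index < 40])

  expect_error(rolling_evaluate(ps, warmup = 10), "warmup")

  # targets with a missing pre-weight are skipped, missing post gives NA error
  ps3 <- ps
  ps3$sessions$pre_weight[36] <- NA   # target index 35
  ps3$sessions$post_weight[40] <- NA  # target index 39
  res3 <- rolling_evaluate(ps3, warmup = 30)
  expect_false(35 %in% res3$target_index)
  expect_true(is.na(res3$abs_error[res3$target_index == 39]))
})

test_that("k_sweep reproduces the single-k run and covers all k", {
  ps <- simulate_patient(simulation_config(n_sessions = 70, seed = 29))
  res <- rolling_evaluate(ps, k = 5, warmup = 30)
  tab <- k_sweep(ps, c(3, 5), warmup = 30)
  expect_equal(tab$k, c(3, 5))
  q <- metric_quad(res$post_actual, res$post_pred)
  expect_equal(tab$mae[2], q$mae)
  expect_equal(tab$r2[2], q$r2)
  expect_true(all(is.finite(tab$mae)))
})

test_that("model JSON round trip preserves predictions exactly", {
  ps <- make_complete_series(60, seed = 31)
  st <- fit_emd_model(ps, k = 3, n = 4, tau = 0.7, trim_rate = 0.1)
  f <- tempfile(fileext = ".json")
  write_emd_model(st, f)
  back <- read_emd_model(f)
  x <- build_features(ps, 3, 50)
  expect_equal(predict_emd(back, x, quiet = TRUE),
               predict_emd(st, x, quiet = TRUE))
  expect_equal(back$base_coefs, unname(st$base_coefs))
})
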