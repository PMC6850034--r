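test_that("compute_delta averages the weight draft over complete sessions", {
  one <- patient_series("p", as.Date("2020-01-01"), 62.5, 60.0, 2000)
  st <- compute_delta(one)
  expect_equal(st$delta, 0.5)
  expect_equal(st$m, 1L)

  two <- patient_series("p", as.Date("2020-01-01") + c(0, 2),
                        c(62.2, 62.4), c(60.0, 60.0), c(2000, 2000))
  expect_equal(compute_delta(two)$delta, 0.3)

  exact <- patient_series("p", as.Date("2020-01-01") + c(0, 2),
                          c(62.0, 61.5), c(60.0, 59.5), c(2000, 2000))
  expect_equal(compute_delta(exact)$delta, 0)

  none <- patient_series("p", as.Date("2020-01-01") + c(0, 2),
                         c(NA, 62), c(60, NA), c(2000, 2000))
  expect_error(compute_delta(none), "no complete sessions")
})

test_that("impute_missing fills pre, inverts for post, drops double-missing", {
  ps <- patient_series("p", as.Date("2020-01-01") + c(0, 2, 4, 6),
                       c(62.5, NA, 62.5, NA),
                       c(60.0, 60.0, NA, NA),
                       c(2000, 2000, 2000, 1500))
  st <- compute_delta(ps)           # only session 1 complete: delta = 0.5
  expect_equal(st$delta, 0.5)
  out <- impute_missing(ps, st)
  s <- out$sessions
  expect_equal(nrow(s), 3)                       # double-missing discarded
  expect_equal(s$session_index, 0:2)
  expect_equal(s$pre_weight[2], 60.0 + 2 + 0.5)  # post + uf/1000 + delta
  expect_equal(s$post_weight[3], 62.5 - 2 - 0.5) # algebraic inversion
  # re-applying the imputation identity to the inverted value recovers pre
  expect_equal(s$post_weight[3] + s$uf_ml[3] / 1000 + st$delta,
               s$pre_weight[3])
})

test_that("imputation residual is exactly zero on every imputed session", {
  for (seed in 1:10) {
    ps <- make_random_table(1, 15, seed = seed, missing = TRUE)[[1]]
    st <- compute_delta(ps)
    pre_na <- is.na(ps$sessions$pre_weight)
    post_na <- is.na(ps$sessions$post_weight)
    out <- impute_missing(ps, st)
    s <- out$sessions
    expect_false(anyNA(s$pre_weight) || anyNA(s$post_weight))
    # re-applying the imputation equation reproduces the stored value bitwise
    ip <- s$date %in% ps$sessions$date[pre_na & !post_na]
    expect_identical(s$pre_weight[ip],
                     s$post_weight[ip] + s$uf_ml[ip] / 1000 + st$delta)
    iq <- s$date %in% ps$sessions$date[post_na & !pre_na]
    expect_identical(s$post_weight[iq],
                     s$pre_weight[iq] - s$uf_ml[iq] / 1000 - st$delta)
  }
})

test_that("trim_outliers removes floor(rate*m) per side, keeps order", {
  ps20 <- make_complete_series(20, seed = 1)
  out <- trim_outliers(ps20, 0.10)
  expect_equal(nrow(out$sessions), 16)

  ps10 <- make_complete_series(10, seed = 2)
  expect_equal(nrow(trim_outliers(ps10, 0.10)$sessions), 8)
  expect_equal(trim_outliers(ps10, 0)$sessions, ps10$sessions)
  expect_error(trim_outliers(ps10, 0.5), "rate")
  expect_error(trim_outliers(ps10, -0.1), "rate")

  for (seed in 1:8) {
    m <- sample(10:40, 1)
    rate <- runif(1, 0, 0.3)
    ps <- make_complete_series(m, seed = seed)
    out <- trim_outliers(ps, rate)
    expect_equal(nrow(out$sessions), m - 2 * floor(rate * m))
    expect_true(!is.unsorted(out$sessions$date, strictly = TRUE))
    # survivors exclude the extreme weight differences
    d_all <- ps$sessions$pre_weight - ps$sessions$post_weight
    d_kept <- out$sessions$pre_weight - out$sessions$post_weight
    n_cut <- floor(rate * m)
    if (n_cut > 0) {
      expect_true(min(d_kept) >= sort(d_all)[n_cut])
      expect_true(max(d_kept) <= sort(d_all, decreasing = TRUE)[n_cut])
    }
  }
})

test_that("build_features assembles 3k+1 recent-first predictors", {
  ps <- make_complete_series(12, seed = 3)
  x <- build_features(ps, k = 5, t = 7)
  expect_length(x, 16)
  expect_equal(attr(x, "target_index"), 7)
  s <- ps$sessions
  expect_equal(unname(x["w0_pre"]), s$pre_weight[8])
  expect_equal(unname(x["pre_1"]), s$pre_weight[7])    # most recent first
  expect_equal(unname(x["post_5"]), s$post_weight[3])
  expect_equal(unname(x["uf_2"]), s$uf_ml[6])

  ps2 <- patient_series("q", as.Date("2020-01-01") + c(0, 2),
                        c(62, 61.5), c(60, 59.8), c(2000, 1900))
  x1 <- build_features(ps2, k = 1, t = 1)
  expect_equal(as.numeric(x1), c(61.5, 62, 60, 2000))

  expect_error(build_features(ps, k = 5, t = 4), "insufficient history")
})

test_that("z-score normalization uses the population convention", {
  expect_equal(drop(apply_norm(matrix(c(1, 3), ncol = 1),
                               fit_norm(matrix(c(1, 3), ncol = 1)))),
               c(-1, 1))
  cst <- matrix(5, nrow = 3, ncol = 1)
  expect_equal(drop(apply_norm(cst, fit_norm(cst))), c(0, 0, 0))

  X <- matrix(rnorm(40, 60, 4), ncol = 4)
  st <- fit_norm(X)
  expect_equal(unname(apply_norm(st$mean, st)), rep(0, 4))

  Z <- apply_norm(X, st)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(colMeans(Z^2) - 1) < 1e-10))

  expect_error(fit_norm(matrix(numeric(0), ncol = 2)), ">= 2 training rows")
  expect_error(apply_norm(1:3, st), "mismatch")
})
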