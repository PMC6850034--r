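#' Exponential-moving-average weight factors
#'
#' Time-attenuated weights for an EMA over the `n` most recent values, with
#' decay ratio `rho = (n - 1) / (n + 1)`. Two conventions are shipped:
#'
#' * `"normalized"` (default): `alpha_i = rho^i / sum_{j=1..n} rho^j`, a
#'   proper convex average (weights sum to 1).
#' * `"literal"`: `alpha_1 = rho` and, for `i > 1`,
#'   `alpha_i = rho^i / (1 + S)` with `S = sum_{j=1..n} rho^j`. These weights
#'   do not sum to 1; the mode is retained for fidelity to the original
#'   piecewise definition.
#'
#' Position 1 is the most recent value.
#'
#' @param n Window length, an integer `>= 2` (`n = 1` gives `rho = 0` and is
#'   rejected as a degenerate decay).
#' @param mode `"normalized"` or `"literal"`.
#' @return A list of class `ema_weights`: `n`, `rho`, `alphas`, `mode`.
#' @export
#' @examples
#' ema_weights(2)$alphas           # 0.75 0.25
#' sum(ema_weights(7)$alphas)      # 1
ema_weights <- function(n, mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 2)
    stop("EMA window n must be an integer >= 2")
  n <- as.integer(n)
  rho <- (n - 1) / (n + 1)
  pow <- rho^seq_len(n)
  s <- sum(pow)
  alphas <- switch(mode,
    normalized = pow / s,
    literal = c(rho, pow[-1] / (1 + s))
  )
  structure(list(n = n, rho = rho, alphas = alphas, mode = mode),
            class = "ema_weights")
}

#' Exponential moving average of a recent-first series
#'
#' @param values Numeric vector of length `n`, most recent value first.
#' @param weights An [ema_weights()] object.
#' @return The weighted sum `sum(alpha_i * values_i)`.
#' @export
ema <- function(values, weights) {
  stopifnot(inherits(weights, "ema_weights"))
  if (length(values) != weights$n)
    stop("length mismatch: ", length(values), " values for EMA window n = ",
         weights$n)
  sum(weights$alphas * values)
}

#' EMA-difference (EMD) transform of a post-dialysis weight series
#'
#' For every session `t` with at least `n` prior sessions, computes the EMA
#' of the `n` strictly prior post-dialysis weights and the detrended target
#' `emd_t = post_t - EMA(post_{t-1}, ..., post_{t-n})`. The EMA excludes the
#' target session: at prediction time the current post-dialysis weight is
#' unknown, so the EMA must be a known quantity.
#'
#' @param series A complete [patient_series()] of length `> n`.
#' @param n EMA window length.
#' @param mode EMA weight mode, see [ema_weights()].
#' @return A data frame with columns `index` (0-based target session),
#'   `ema_value` and `emd` (kg).
#' @export
emd_series <- function(series, n, mode = c("normalized", "literal")) {
  w <- ema_weights(n, mode)
  s <- series$sessions
  m <- nrow(s)
  if (m <= n) stop("series of length ", m, " too short for EMA window ", n)
  if (anyNA(s$post_weight)) stop("EMD requires a complete series")
  idx <- n:(m - 1)                       # 0-based targets
  ema_v <- vapply(idx, function(t) {
    ema(s$post_weight[t + 1 - seq_len(n)], w)
  }, numeric(1))
  data.frame(index = idx, ema_value = ema_v,
             emd = s$post_weight[idx + 1] - ema_v)
}

# Minimum-norm least squares via SVD; optional observation weights.
# Returns list(coef, rank).
lsq_minnorm <- function(A, y, w = NULL, tol = 1e-10) {
  if (!is.null(w)) {
    sw <- sqrt(w)
    A <- A * sw
    y <- y * sw
  }
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d, .Machine$double.eps)
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  list(coef = drop(coef), rank = sum(pos))
}

#' Fit the two-stage EMD weight model
#'
#' Stage one fits, by least squares, a global linear model of the EMD target
#' (see [emd_series()]) on the z-score-normalized `3k + 1` feature vector of
#' [build_features()]. Stage two — performed lazily at prediction time by
#' [predict_emd()] — corrects the baseline with a Gaussian-kernel locally
#' weighted regression of the training residuals, so the fitted state retains
#' the normalized training matrix and targets.
#'
#' Outlier trimming removes the training rows whose *target* session falls in
#' the extreme `trim_rate` tails of the intradialytic weight difference (see
#' [trim_outliers()]); feature histories and EMA windows are built on the
#' full series so that lag structure stays intact.
#'
#' @param series A complete (imputed) [patient_series()].
#' @param k Feature history depth (default 5, i.e. 16 features).
#' @param n EMA window length (default 5).
#' @param tau Gaussian kernel bandwidth in normalized-feature units
#'   (default 1.0).
#' @param ema_mode EMA weight convention, see [ema_weights()].
#' @param kernel_mode `"sample_weight"` (training rows weighted by a kernel
#'   on the whole normalized feature vector; default) or `"elementwise"`
#'   (per-feature kernel scaling of the design matrix).
#' @param trim_rate Per-side trimming rate for training rows (default 0.10).
#' @param quiet Suppress the rank-deficiency warning (used by the rolling
#'   protocol, where collinear feature histories are routine).
#' @return An object of class `emd_model`.
#' @export
fit_emd_model <- function(series, k = 5, n = 5, tau = 1.0,
                          ema_mode = c("normalized", "literal"),
                          kernel_mode = c("sample_weight", "elementwise"),
                          trim_rate = 0.10, quiet = FALSE) {
  ema_mode <- match.arg(ema_mode)
  kernel_mode <- match.arg(kernel_mode)
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  validate_patient_series(series)
  s <- series$sessions
  if (anyNA(s$pre_weight) || anyNA(s$post_weight))
    stop("fit requires a complete (imputed) series")
  m <- nrow(s)
  t0 <- max(k, n)
  if (m - t0 < 1) stop("series too short for k = ", k, ", n = ", n)

  targets <- t0:(m - 1)
  X <- build_feature_matrix(series, k, targets)
  ed <- emd_series(series, n, ema_mode)
  stopifnot(identical(ed$index, targets))
  y <- ed$emd

  keep_session <- trim_keep_mask(series, trim_rate)
  keep <- keep_session[targets + 1]
  X <- X[keep, , drop = FALSE]
  y <- y[keep]

  p <- 3 * k + 1
  if (nrow(X) < p + 1)
    stop("too few training rows after trimming: ", nrow(X),
         " < ", p + 1, " (need 3k + 2)")

  ns <- fit_norm(X)
  Xn <- apply_norm(X, ns)
  fitls <- lsq_minnorm(cbind(1, Xn), y)
  if (!quiet && fitls$rank < p + 1)
    warning("rank-deficient design (rank ", fitls$rank, " < ", p + 1,
            "); minimum-norm least-squares solution used", call. = FALSE)
  base_pred <- drop(cbind(1, Xn) %*% fitls$coef)

  structure(list(
    k = k, n = n, tau = tau, ema_mode = ema_mode, kernel_mode = kernel_mode,
    trim_rate = trim_rate,
    norm_stats = ns,
    base_coefs = fitls$coef,           # intercept first
    training_features = Xn,
    training_emd = y,
    training_resid = y - base_pred
  ), class = "emd_model")
}

#' @export
print.emd_model <- function(x, ...) {
  cat(sprintf(paste0("<emd_model> k=%d n=%d tau=%g ema=%s kernel=%s  ",
                     "%d training rows\n"),
              x$k, x$n, x$tau, x$ema_mode, x$kernel_mode,
              nrow(x$training_features)))
  invisible(x)
}

#' Predict the EMD value for one feature vector
#'
#' Computes the global linear baseline `emd_base` and the Gaussian-kernel
#' local correction `emd_delta`, returning `emd_pred = emd_base + emd_delta`.
#'
#' In `"sample_weight"` mode every retained training row `j` receives weight
#' `exp(-||x_j - x||^2 / (2 tau^2))` (normalized features) and the baseline
#' residuals are refit by weighted least squares, evaluated at the query.
#' When the effective sample size `sum(w_j)` falls below the feature count
#' plus one, the kernel is too narrow to support a regression and the
#' correction falls back to 0 (with a warning unless `quiet`).
#' In `"elementwise"` mode each design entry is scaled by a per-feature
#' kernel factor before an unweighted refit.
#'
#' @param state A fitted [fit_emd_model()] object.
#' @param x Raw (unnormalized) feature vector from [build_features()].
#' @param quiet Suppress the degenerate-kernel warning.
#' @return A list with `emd_base`, `emd_delta`, `emd_pred` (kg).
#' @export
predict_emd <- function(state, x, quiet = FALSE) {
  stopifnot(inherits(state, "emd_model"))
  if (length(x) != 3 * state$k + 1)
    stop("feature vector must have length ", 3 * state$k + 1)
  if (any(!is.finite(x))) stop("non-finite feature value")
  xn <- apply_norm(as.numeric(x), state$norm_stats)
  emd_base <- state$base_coefs[1] + sum(state$base_coefs[-1] * xn)

  Xn <- state$training_features
  r <- state$training_resid
  p1 <- ncol(Xn) + 1
  tau <- state$tau

  if (state$kernel_mode == "sample_weight") {
    d2 <- rowSums(sweep(Xn, 2, xn)^2)
    w <- exp(-d2 / (2 * tau^2))
    if (sum(w) < p1) {
      if (!quiet)
        warning("degenerate kernel (effective sample size ",
                format(sum(w), digits = 3), " < ", p1,
                "): local correction set to 0", call. = FALSE)
      emd_delta <- 0
    } else {
      cf <- lsq_minnorm(cbind(1, Xn), r, w = w)$coef
      emd_delta <- cf[1] + sum(cf[-1] * xn)
    }
  } else {
    K <- exp(-sweep(Xn, 2, xn)^2 / (2 * tau^2))
    cf <- lsq_minnorm(cbind(1, Xn * K), r)$coef
    emd_delta <- cf[1] + sum(cf[-1] * xn)   # query kernel factor is 1
  }
  list(emd_base = unname(emd_base), emd_delta = unname(emd_delta),
       emd_pred = unname(emd_base + emd_delta))
}

# prediction core shared by predict_post and rolling_evaluate:
# history = complete session table providing the k/n most recent records,
# pre_t = target pre-dialysis weight, post_t = actual post weight (or NA)
predict_from_history <- function(state, history, pre_t, post_t, target_index,
                                 quiet = FALSE) {
  k <- state$k; n <- state$n
  mh <- nrow(history)
  if (mh < max(k, n)) stop("insufficient history: ", mh, " prior sessions")
  hist_rows <- mh + 1 - seq_len(k)                      # recent first
  x <- c(pre_t, history$pre_weight[hist_rows], history$post_weight[hist_rows],
         history$uf_ml[hist_rows])
  wts <- ema_weights(n, state$ema_mode)
  ema_value <- ema(history$post_weight[mh + 1 - seq_len(n)], wts)
  pr <- predict_emd(state, x, quiet = quiet)
  post_pred <- ema_value + pr$emd_pred
  abs_error <- if (is.na(post_t)) NA_real_ else abs(post_pred - post_t)
  rel_error <- if (is.na(post_t)) NA_real_ else abs_error / post_t
  data.frame(target_index = target_index, ema_value = ema_value,
             emd_base = pr$emd_base, emd_delta = pr$emd_delta,
             emd_pred = pr$emd_pred, post_pred = post_pred,
             post_actual = post_t, abs_error = abs_error,
             rel_error = rel_error)
}

#' Predict the post-dialysis weight of one session
#'
#' Reconstructs the post-dialysis weight as `EMA(prior post-weights) +
#' emd_pred`: the EMA of the `n` strictly prior post-dialysis weights is a
#' known quantity at prediction time, and the model supplies the detrended
#' increment.
#'
#' @param state A fitted [fit_emd_model()].
#' @param series A [patient_series()]; sessions `t - max(k, n) .. t - 1` must
#'   be complete and the target's pre-dialysis weight must be present.
#' @param t 0-based target session index.
#' @param quiet Suppress degenerate-kernel warnings.
#' @return A one-row data frame: `target_index`, `ema_value`, `emd_base`,
#'   `emd_delta`, `emd_pred`, `post_pred`, `post_actual`, `abs_error`,
#'   `rel_error` (errors `NA` when the actual post-weight is unknown).
#' @export
predict_post <- function(state, series, t, quiet = FALSE) {
  stopifnot(inherits(state, "emd_model"))
  s <- series$sessions
  if (t < max(state$k, state$n) || t > nrow(s) - 1)
    stop("insufficient history for target index ", t)
  pre_t <- s$pre_weight[t + 1]
  if (is.na(pre_t)) stop("target session ", t, " has no pre-dialysis weight")
  predict_from_history(state, s[seq_len(t), , drop = FALSE], pre_t,
                       s$post_weight[t + 1], t, quiet = quiet)
}

#' Rolling-origin evaluation of the two-stage model
#'
#' For every target session `t` from `warmup` to the end of the series, the
#' entire pipeline — imputation statistics, imputation, outlier trimming,
#' normalization and both regression stages — is refit on the sessions
#' strictly before `t`, and session `t` is then predicted. Nothing at or
#' after `t` can influence the prediction at `t`.
#'
#' Targets whose pre-dialysis weight is missing cannot be featurized and are
#' skipped; targets with a missing post-dialysis weight are predicted but
#' carry `NA` errors.
#'
#' @param series A [patient_series()] (may contain missing weights).
#' @param k,n,tau,ema_mode,kernel_mode,trim_rate Model hyperparameters, see
#'   [fit_emd_model()].
#' @param warmup First target index (default 30); must leave enough training
#'   rows (`warmup >= max(k, n) + 3k + 2`).
#' @return A data frame of per-target prediction rows (see [predict_post()])
#'   with the configuration attached as attribute `config`.
#' @export
rolling_evaluate <- function(series, k = 5, n = 5, tau = 1.0,
                             ema_mode = c("normalized", "literal"),
                             kernel_mode = c("sample_weight", "elementwise"),
                             warmup = 30, trim_rate = 0.10) {
  ema_mode <- match.arg(ema_mode)
  kernel_mode <- match.arg(kernel_mode)
  validate_patient_series(series)
  m <- nrow(series$sessions)
  min_warm <- max(k, n) + 3 * k + 2
  if (warmup < min_warm)
    stop("warmup ", warmup, " too small: need at least ", min_warm)
  if (m <= warmup) stop("series of length ", m, " has no targets past warmup ",
                        warmup)
  out <- vector("list", m - warmup)
  for (t in warmup:(m - 1)) {
    pre_t <- series$sessions$pre_weight[t + 1]
    if (is.na(pre_t)) next
    prefix <- series_prefix(series, t)
    prefix <- impute_missing(prefix)
    state <- fit_emd_model(prefix, k = k, n = n, tau = tau,
                           ema_mode = ema_mode, kernel_mode = kernel_mode,
                           trim_rate = trim_rate, quiet = TRUE)
    out[[t - warmup + 1]] <- predict_from_history(
      state, prefix$sessions, pre_t, series$sessions$post_weight[t + 1], t,
      quiet = TRUE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no predictable targets past warmup")
  rownames(res) <- NULL
  attr(res, "config") <- list(k = k, n = n, tau = tau, ema_mode = ema_mode,
                              kernel_mode = kernel_mode, warmup = warmup,
                              trim_rate = trim_rate)
  res
}

#' Sweep the feature history depth k
#'
#' Runs [rolling_evaluate()] for each value of `k` on every series and pools
#' the (actual, predicted) post-dialysis weight pairs across patients into
#' one [metric_quad()] per `k`.
#'
#' @param series_list A `patient_series` or list of them.
#' @param k_values Integer vector of history depths (e.g. `1:10`).
#' @param ... Passed to [rolling_evaluate()] (everything except `k`).
#' @return A data frame with columns `k`, `mae`, `mape`, `mse`, `r2`.
#' @export
k_sweep <- function(series_list, k_values, ...) {
  if (inherits(series_list, "patient_series")) series_list <- list(series_list)
  rows <- lapply(k_values, function(k) {
    res <- do.call(rbind, lapply(series_list, rolling_evaluate, k = k, ...))
    res <- res[!is.na(res$post_actual), , drop = FALSE]
    q <- metric_quad(res$post_actual, res$post_pred)
    data.frame(k = k, mae = q$mae, mape = q$mape, mse = q$mse, r2 = q$r2)
  })
  do.call(rbind, rows)
}

#' Serialize a fitted model to JSON
#'
#' Writes every fitted artifact (hyperparameters, normalization statistics,
#' baseline coefficients, retained training arrays) to a single JSON
#' document so the model can be fit once and applied later.
#'
#' @param state A fitted [fit_emd_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emd_model <- function(state, path) {
  stopifnot(inherits(state, "emd_model"))
  doc <- list(
    format = "hdweight/emd_model/1",
    k = state$k, n = state$n, tau = state$tau,
    ema_mode = state$ema_mode, kernel_mode = state$kernel_mode,
    trim_rate = state$trim_rate,
    norm_mean = unname(state$norm_stats$mean),
    norm_sd = unname(state$norm_stats$sd),
    base_coefs = unname(state$base_coefs),
    training_features = unname(state$training_features),
    training_emd = unname(state$training_emd)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a fitted model from JSON
#'
#' @param path Path written by [write_emd_model()].
#' @return An `emd_model` object.
#' @export
read_emd_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hdweight/emd_model/1"))
    stop("not an hdweight model file: ", path)
  ns <- structure(list(mean = doc$norm_mean, sd = doc$norm_sd),
                  class = "norm_stats")
  Xn <- as.matrix(doc$training_features)
  base_pred <- drop(cbind(1, Xn) %*% doc$base_coefs)
  structure(list(
    k = doc$k, n = doc$n, tau = doc$tau, ema_mode = doc$ema_mode,
    kernel_mode = doc$kernel_mode, trim_rate = doc$trim_rate,
    norm_stats = ns, base_coefs = doc$base_coefs,
    training_features = Xn, training_emd = doc$training_emd,
    training_resid = doc$training_emd - base_pred
  ), class = "emd_model")
}
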