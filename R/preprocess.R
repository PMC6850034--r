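#' Average weight draft of a patient series
#'
#' The weight draft of a complete session is
#' `pre_weight - post_weight - uf_ml/1000`: the part of the intradialytic
#' weight change not explained by the prescribed ultrafiltration (saline
#' supplementation at end of session, residual excretion). Its mean over all
#' complete sessions, delta, is the imputation constant for missing weights.
#'
#' @param series A [patient_series()].
#' @return A list of class `imputation_stats`: `delta` (kg) and `m`, the
#'   number of complete sessions used.
#' @export
#' @examples
#' ps <- patient_series("p", as.Date("2020-01-01") + 0:1,
#'                      c(62.5, 62.2), c(60.0, 60.0), c(2000, 1800))
#' compute_delta(ps)  # mean of 0.5 and 0.4
compute_delta <- function(series) {
  validate_patient_series(series)
  s <- series$sessions
  ok <- !is.na(s$pre_weight) & !is.na(s$post_weight)
  m <- sum(ok)
  if (m < 1)
    stop("no complete sessions: cannot compute the average weight draft for ",
         series$patient_id)
  delta <- mean(s$pre_weight[ok] - s$post_weight[ok] - s$uf_ml[ok] / 1000)
  structure(list(delta = delta, m = m), class = "imputation_stats")
}

#' Impute missing session weights from the average weight draft
#'
#' Sessions missing both weights are discarded. A missing pre-dialysis weight
#' is reconstructed as `post + uf/1000 + delta`; a missing post-dialysis
#' weight by the algebraic inversion `pre - uf/1000 - delta`. The returned
#' series has no missing weights and a reassigned 0-based session index.
#'
#' @param series A [patient_series()].
#' @param stats An `imputation_stats` from [compute_delta()]; computed from
#'   `series` when omitted.
#' @return The imputed `patient_series`.
#' @export
impute_missing <- function(series, stats = compute_delta(series)) {
  stopifnot(inherits(stats, "imputation_stats"))
  s <- series$sessions
  both <- is.na(s$pre_weight) & is.na(s$post_weight)
  s <- s[!both, , drop = FALSE]
  mp <- is.na(s$pre_weight)
  s$pre_weight[mp] <- s$post_weight[mp] + s$uf_ml[mp] / 1000 + stats$delta
  mq <- is.na(s$post_weight)
  s$post_weight[mq] <- s$pre_weight[mq] - s$uf_ml[mq] / 1000 - stats$delta
  out <- replace_sessions(series, s)
  validate_patient_series(out)
  out
}

# logical keep-mask for per-side trimming on (pre - post); stable on ties
trim_keep_mask <- function(series, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 0.5)
    stop("trim rate must lie in [0, 0.5)")
  s <- series$sessions
  if (anyNA(s$pre_weight) || anyNA(s$post_weight))
    stop("trim requires a complete (imputed) series")
  m <- nrow(s)
  n_cut <- floor(rate * m)
  keep <- rep(TRUE, m)
  if (n_cut > 0) {
    ord <- order(s$pre_weight - s$post_weight)  # stable: ties keep temporal order
    keep[ord[seq_len(n_cut)]] <- FALSE
    keep[ord[m - n_cut + seq_len(n_cut)]] <- FALSE
  }
  keep
}

#' Trim sessions with extreme intradialytic weight differences
#'
#' Sorts sessions by `pre_weight - post_weight` and removes `floor(rate * m)`
#' sessions from each extreme (default 10% per side), returning the survivors
#' in their original temporal order. Intended for training data only;
#' evaluation targets are never trimmed.
#'
#' @param series A complete (imputed) [patient_series()].
#' @param rate Fraction removed per side, in `[0, 0.5)`.
#' @return The trimmed `patient_series` (session index reassigned).
#' @export
trim_outliers <- function(series, rate = 0.10) {
  validate_patient_series(series)
  keep <- trim_keep_mask(series, rate)
  replace_sessions(series, series$sessions[keep, , drop = FALSE])
}

#' Build the feature vector for one target session
#'
#' The predictors for session `t` are the current pre-dialysis weight plus
#' the `k` most recent prior pre-dialysis weights, post-dialysis weights and
#' UF volumes — `3k + 1` features in total (16 at the default `k = 5`).
#' Histories are ordered most-recent-first: position 1 is session `t - 1`.
#'
#' @param series A complete [patient_series()].
#' @param k History depth (number of prior sessions per variable).
#' @param t 0-based index of the target session; must satisfy `t >= k`.
#' @return A named numeric vector `(w0_pre, pre_1..pre_k, post_1..post_k,
#'   uf_1..uf_k)` with attribute `target_index = t`.
#' @export
build_features <- function(series, k, t) {
  s <- series$sessions
  m <- nrow(s)
  if (k < 1) stop("k must be >= 1")
  if (t < k) stop("insufficient history: target index ", t, " < k = ", k)
  if (t > m - 1) stop("target index ", t, " beyond series of length ", m)
  rows <- (t + 1)  # R row of session t
  hist <- rows - seq_len(k)  # t-1 .. t-k, recent first
  x <- c(s$pre_weight[rows], s$pre_weight[hist], s$post_weight[hist],
         s$uf_ml[hist])
  if (anyNA(x)) stop("features require complete weights at sessions ",
                     t - k, "..", t)
  names(x) <- c("w0_pre", paste0("pre_", seq_len(k)),
                paste0("post_", seq_len(k)), paste0("uf_", seq_len(k)))
  attr(x, "target_index") <- t
  x
}

# all eligible feature rows (targets t0..m-1) as a matrix; fast path used by fit
build_feature_matrix <- function(series, k, targets) {
  X <- t(vapply(targets, function(t) build_features(series, k, t),
                numeric(3 * k + 1)))
  rownames(X) <- targets
  X
}

#' Fit z-score normalization statistics
#'
#' Per-feature mean and population (divide-by-m) standard deviation on a
#' training matrix. Columns with standard deviation below `1e-12` are marked
#' degenerate and map to 0 under [apply_norm()].
#'
#' @param x Numeric training matrix, one row per training example (>= 2 rows).
#' @return A list of class `norm_stats` with `mean` and `sd` vectors.
#' @export
fit_norm <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 training rows to fit normalization")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population convention
  structure(list(mean = mu, sd = sdv), class = "norm_stats")
}

#' Apply z-score normalization
#'
#' @param x Numeric vector (one example) or matrix (rows = examples) with the
#'   same feature count as the training matrix.
#' @param stats A `norm_stats` from [fit_norm()].
#' @return The normalized vector or matrix; degenerate columns
#'   (training sd < 1e-12) are set to 0.
#' @export
apply_norm <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(stats$mean))
    stop("feature count mismatch: ", ncol(x), " vs ", length(stats$mean))
  live <- stats$sd >= 1e-12
  z <- sweep(x, 2, stats$mean)
  z[, live] <- sweep(z[, live, drop = FALSE], 2, stats$sd[live], "/")
  z[, !live] <- 0
  if (vec) drop(z) else z
}
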