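#' MAE / MAPE / MSE / r-squared metric quadruple
#'
#' Errors are `actual - predicted`. MAE, MSE and `r2 = 1 - SSE/SST` use the
#' pairs directly; MAPE is `mean(|error| / denominator) * 100`. By default
#' the denominator is the actual post-dialysis weight (the clinical
#' relative-error convention); pass `denominators = actual` values of the
#' detrended EMD target for the literal EMD-denominator form.
#'
#' @param actual Numeric vector of observed values (kg).
#' @param predicted Numeric vector of predictions, same length.
#' @param denominators MAPE denominators; default `actual`.
#' @return A list of class `metric_quad`: `mae` (kg), `mape` (percent),
#'   `mse` (kg^2), `r2`. `r2` is `NaN` (with a warning) when the actuals are
#'   constant.
#' @export
#' @examples
#' metric_quad(c(60, 61), c(60.1, 60.7))
metric_quad <- function(actual, predicted, denominators = actual) {
  n <- length(actual)
  if (n == 0) stop("empty input")
  if (length(predicted) != n || length(denominators) != n)
    stop("length mismatch: actual ", n, ", predicted ", length(predicted),
         ", denominators ", length(denominators))
  e <- actual - predicted
  sst <- sum((actual - mean(actual))^2)
  r2 <- if (sst < .Machine$double.eps * n) {
    warning("constant actual values: r2 undefined", call. = FALSE)
    NaN
  } else 1 - sum(e^2) / sst
  structure(list(mae = mean(abs(e)),
                 mape = mean(abs(e) / abs(denominators)) * 100,
                 mse = mean(e^2),
                 r2 = r2),
            class = "metric_quad")
}

#' @export
print.metric_quad <- function(x, ...) {
  cat(sprintf("MAE %.4f kg  MAPE %.4f%%  MSE %.4f kg^2  r2 %.4f\n",
              x$mae, x$mape, x$mse, x$r2))
  invisible(x)
}

# gamma MLE with location fixed at 0, via Newton on the shape equation
# log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))
gamma_mle <- function(x, max_iter = 100L, tol = 1e-12) {
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) s <- .Machine$double.eps  # numerically constant sample
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in seq_len(max_iter)) {
    g <- log(shape) - digamma(shape) - s
    step <- g / (1 / shape - trigamma(shape))
    shape <- shape - step
    if (abs(step) < tol * shape) break
  }
  list(shape = shape, scale = mean(x) / shape)
}

#' Gamma calibration of a prediction-error sample
#'
#' Fits a gamma distribution (location fixed at 0) to nonnegative prediction
#' errors by maximum likelihood and evaluates its CDF at a clinical
#' threshold — e.g. 0.5 kg for absolute errors or 0.01 for relative errors.
#' Exact zeros are clipped to `1e-6` to keep the log-likelihood finite.
#'
#' @param errors Nonnegative numeric vector with at least 10 positive values.
#' @param threshold Threshold at which to evaluate the fitted CDF.
#' @return A list of class `gamma_error_fit`: `shape`, `scale`, `threshold`,
#'   `cdf_at_threshold`, `n`. If every error is zero the fit is degenerate
#'   and the CDF is reported as 1 with a warning.
#' @export
error_cdf <- function(errors, threshold) {
  errors <- errors[!is.na(errors)]
  if (any(errors < 0)) stop("errors must be nonnegative")
  if (all(errors == 0)) {
    warning("all errors are zero: degenerate gamma fit", call. = FALSE)
    return(structure(list(shape = NA_real_, scale = NA_real_,
                          threshold = threshold, cdf_at_threshold = 1,
                          n = length(errors)),
                     class = "gamma_error_fit"))
  }
  if (sum(errors > 0) < 10)
    stop("need at least 10 positive errors for a gamma fit")
  x <- pmax(errors, 1e-6)
  fit <- gamma_mle(x)
  structure(list(shape = fit$shape, scale = fit$scale, threshold = threshold,
                 cdf_at_threshold = stats::pgamma(threshold,
                                                  shape = fit$shape,
                                                  scale = fit$scale),
                 n = length(x)),
            class = "gamma_error_fit")
}

#' @export
print.gamma_error_fit <- function(x, ...) {
  cat(sprintf("gamma(shape %.3f, scale %.4f), n=%d: P(err <= %g) = %.4f\n",
              x$shape, x$scale, x$n, x$threshold, x$cdf_at_threshold))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from group sums of squares.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return A list with `f_stat`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  all_x <- unlist(groups, use.names = FALSE)
  if (anyNA(all_x)) stop("missing values in groups")
  gm <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum(vapply(seq_along(groups),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(all_x) - length(groups)
  if (ssw == 0 && ssb == 0) stop("all values identical: ANOVA degenerate")
  f <- (ssb / dfb) / (ssw / dfw)
  list(f_stat = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw)
}

#' Holm-adjusted t-test comparisons against a reference method
#'
#' Runs a t-test of the reference metric sample against each competing
#' method's sample (paired by default: one metric value per patient per
#' method, same patients throughout) and applies the Holm step-down
#' adjustment to the raw p-values. Samples that are identical to the
#' reference give `t = 0`, `p = 1` rather than a degenerate test.
#'
#' @param reference Numeric metric vector for the reference method.
#' @param others Named list of metric vectors for the competing methods.
#' @param alpha Family-wise error rate for the reject flags (default 0.05).
#' @param paired Paired t-tests (requires equal lengths); default `TRUE`.
#' @return A data frame with one row per comparison: `method`, `t_stat`,
#'   `p_raw`, `p_holm`, `reject`.
#' @export
holm_ttests <- function(reference, others, alpha = 0.05, paired = TRUE) {
  if (!is.list(others) || is.null(names(others)) || any(!nzchar(names(others))))
    stop("others must be a named list of metric vectors")
  res <- lapply(names(others), function(nm) {
    x <- others[[nm]]
    if (paired && length(x) != length(reference))
      stop("paired comparison requires equal lengths (", nm, ")")
    degenerate <- if (paired) all(reference - x == 0) else
      (stats::sd(reference) == 0 && stats::sd(x) == 0 &&
         mean(reference) == mean(x))
    if (degenerate) {
      data.frame(method = nm, t_stat = 0, p_raw = 1)
    } else {
      tt <- stats::t.test(reference, x, paired = paired)
      data.frame(method = nm, t_stat = unname(tt$statistic),
                 p_raw = tt$p.value)
    }
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out$reject <- out$p_holm <= alpha
  out
}

#' Flag sessions whose prediction deviates beyond clinical thresholds
#'
#' A session is flagged when its absolute error exceeds `abs_threshold`
#' (default 0.5 kg) OR its relative error exceeds `rel_threshold`
#' (default 1%). Deviations at this scale are the clinical rule of thumb for
#' an acceptable post-dialysis weight, so a flag marks a weight-adjustment
#' event worth a manual review.
#'
#' @param results Prediction rows from [rolling_evaluate()] or
#'   [predict_post()]; rows without an actual weight are ignored.
#' @param abs_threshold Absolute error threshold in kg.
#' @param rel_threshold Relative error threshold as a fraction.
#' @return The subset of flagged rows, with a `flag_reason` column
#'   (`"abs"`, `"rel"` or `"abs+rel"`).
#' @export
deviation_alert <- function(results, abs_threshold = 0.5,
                            rel_threshold = 0.01) {
  known <- !is.na(results$abs_error)
  r <- results[known, , drop = FALSE]
  fa <- r$abs_error > abs_threshold
  fr <- r$rel_error > rel_threshold
  out <- r[fa | fr, , drop = FALSE]
  out$flag_reason <- paste0(ifelse(fa[fa | fr], "abs", ""),
                            ifelse(fa[fa | fr] & fr[fa | fr], "+", ""),
                            ifelse(fr[fa | fr], "rel", ""))
  rownames(out) <- NULL
  out
}
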