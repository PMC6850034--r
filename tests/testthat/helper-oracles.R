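# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's code paths: literal sums, solve() on normal equations,
# hand-written Holm step-down.

# random complete series with independent pre/post/uf (well-conditioned designs)
make_complete_series <- function(m, seed = 1, id = "p") {
  set.seed(seed)
  patient_series(id, as.Date("2020-01-06") + cumsum(sample(2:3, m, TRUE)),
                 pre_weight = runif(m, 58, 70),
                 post_weight = runif(m, 55, 66),
                 uf_ml = runif(m, 0, 3000))
}

# random valid CSV-resolution table (weights at gram resolution), with
# optional missing weights and group labels
make_random_table <- function(n_patients, m, seed = 1, missing = FALSE) {
  set.seed(seed)
  groups <- c("stabilized", "intolerant", "near_death", "unknown")
  lapply(seq_len(n_patients), function(i) {
    pre <- round(runif(m, 45, 90), 3)
    post <- round(runif(m, 40, 85), 3)
    if (missing && m > 2) {
      pre[sample(m, 1)] <- NA
      post[sample(m, 1)] <- NA
    }
    patient_series(paste0("pat", i),
                   as.Date("2019-03-04") + cumsum(sample(2:4, m, TRUE)),
                   pre, post, round(runif(m, 0, 4000), 3),
                   group = sample(groups, 1))
  })
}

# term-by-term metric sums
oracle_quad <- function(a, p, d = a) {
  n <- length(a)
  e <- a - p
  mae <- 0; mape <- 0; mse <- 0
  for (i in seq_len(n)) {
    mae <- mae + abs(e[i]) / n
    mape <- mape + abs(e[i]) / abs(d[i]) / n * 100
    mse <- mse + e[i]^2 / n
  }
  abar <- sum(a) / n
  list(mae = mae, mape = mape, mse = mse,
       r2 = 1 - sum(e^2) / sum((a - abar)^2))
}

# Holm step-down adjustment, literal definition
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# (weighted) normal equations; full-rank designs only
oracle_ls <- function(A, y, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(A))
  drop(solve(crossprod(A, w * A), crossprod(A, w * y)))
}

# tiny CSV writer for parser tests
write_lines_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
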