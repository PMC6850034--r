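#' @keywords internal
"_PACKAGE"

# Fixed EHR CSV schema. Empty string = missing weight; one row per session.
.hdw_schema <- c("patient_id", "date", "pre_weight_kg", "post_weight_kg", "uf_ml")
.hdw_groups <- c("stabilized", "intolerant", "near_death", "unknown")

#' Construct a per-patient hemodialysis session series
#'
#' A `patient_series` holds the ordered dialysis sessions of one patient:
#' session date, pre- and post-dialysis body weight (kg, possibly missing),
#' and the prescribed ultrafiltration (UF) volume (mL). Sessions are sorted
#' by date and given a 0-based `session_index`.
#'
#' @param patient_id Patient identifier (opaque string).
#' @param date Vector of session dates (`Date` or ISO-8601 strings).
#' @param pre_weight Pre-dialysis weights in kg; `NA` = missing.
#' @param post_weight Post-dialysis weights in kg; `NA` = missing.
#' @param uf_ml Ultrafiltration volumes in mL; nonnegative, never missing.
#' @param group Clinical group label: one of `"stabilized"`, `"intolerant"`,
#'   `"near_death"`, `"unknown"`.
#'
#' @return An object of class `patient_series`: a list with elements
#'   `patient_id`, `group`, and `sessions` (a data frame with columns
#'   `date`, `pre_weight`, `post_weight`, `uf_ml`, `session_index`).
#' @export
#' @examples
#' ps <- patient_series("p1", as.Date("2020-01-01") + c(0, 2, 4),
#'                      pre_weight = c(62.5, 62.1, NA),
#'                      post_weight = c(60.0, 59.9, 60.1),
#'                      uf_ml = c(2000, 1800, 2100))
#' ps$sessions
patient_series <- function(patient_id, date, pre_weight, post_weight, uf_ml,
                           group = "unknown") {
  stopifnot(length(patient_id) == 1L)
  group <- match.arg(group, .hdw_groups)
  date <- as.Date(date)
  m <- length(date)
  if (length(pre_weight) != m || length(post_weight) != m || length(uf_ml) != m)
    stop("date, pre_weight, post_weight and uf_ml must have equal length")
  ord <- order(date)
  sessions <- data.frame(
    date = date[ord],
    pre_weight = as.numeric(pre_weight)[ord],
    post_weight = as.numeric(post_weight)[ord],
    uf_ml = as.numeric(uf_ml)[ord],
    session_index = seq_len(m) - 1L
  )
  out <- structure(
    list(patient_id = as.character(patient_id), group = group,
         sessions = sessions),
    class = "patient_series"
  )
  validate_patient_series(out)
  out
}

#' Validate a patient series against its invariants
#'
#' Checks strictly increasing dates (no duplicate session dates), nonnegative
#' UF volumes, plausible weights (every present weight in the open interval
#' (20, 200) kg), and a 0-based contiguous `session_index`.
#'
#' @param x A `patient_series`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_patient_series <- function(x) {
  if (!inherits(x, "patient_series")) stop("not a patient_series")
  s <- x$sessions
  if (nrow(s) > 0) {
    if (anyDuplicated(s$date))
      stop("duplicate session dates for patient ", x$patient_id)
    if (is.unsorted(s$date, strictly = TRUE))
      stop("session dates must be strictly increasing for patient ",
           x$patient_id)
    if (anyNA(s$uf_ml) || any(s$uf_ml < 0))
      stop("uf_ml must be present and nonnegative for patient ", x$patient_id)
    w <- c(s$pre_weight, s$post_weight)
    bad <- !is.na(w) & (w <= 20 | w >= 200)
    if (any(bad))
      stop("weight outside (20, 200) kg for patient ", x$patient_id, ": ",
           paste(unique(w[bad]), collapse = ", "))
    if (!identical(s$session_index, seq_len(nrow(s)) - 1L))
      stop("session_index must be 0..m-1 for patient ", x$patient_id)
  }
  invisible(x)
}

#' @export
print.patient_series <- function(x, ...) {
  s <- x$sessions
  n_miss <- sum(is.na(s$pre_weight)) + sum(is.na(s$post_weight))
  cat(sprintf("<patient_series> %s  group=%s  %d sessions  %d missing weights\n",
              x$patient_id, x$group, nrow(s), n_miss))
  if (nrow(s) > 0)
    cat(sprintf("  %s .. %s\n", format(s$date[1]), format(s$date[nrow(s)])))
  invisible(x)
}

# number of sessions
#' @export
length.patient_series <- function(x) nrow(x$sessions)

# sub-series of the first `upto` sessions (session_index reassigned 0-based)
series_prefix <- function(series, upto) {
  s <- series$sessions[seq_len(upto), , drop = FALSE]
  replace_sessions(series, s)
}

# rebuild a patient_series around a (subsetted) session table
replace_sessions <- function(series, sessions) {
  sessions$session_index <- seq_len(nrow(sessions)) - 1L
  rownames(sessions) <- NULL
  out <- series
  out$sessions <- sessions
  out
}

#' Read hemodialysis session records from CSV
#'
#' Parses a session table in the fixed schema
#' `patient_id,date,pre_weight_kg,post_weight_kg,uf_ml` (optional sixth
#' column `group`), groups rows by patient, sorts each patient's sessions by
#' date and assigns `session_index` from 0. Empty weight fields are parsed
#' as missing (`NA`); UF must always be present and nonnegative.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @return A named list of [patient_series()], one per patient, in order of
#'   first appearance.
#' @export
#' @seealso [write_hd_sessions()]
read_hd_sessions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  have_group <- "group" %in% names(raw)
  need <- if (have_group) c(.hdw_schema, "group") else .hdw_schema
  if (!identical(names(raw), need))
    stop("bad header: expected columns ", paste(need, collapse = ","),
         " but found ", paste(names(raw), collapse = ","))
  n <- nrow(raw)
  if (n == 0) return(structure(list(), names = character(0)))

  line_no <- seq_len(n) + 1L  # header is line 1

  parse_num <- function(txt, field, allow_empty) {
    empty <- !nzchar(txt)
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(!empty & is.na(out))
    if (length(bad))
      stop(sprintf("line %d: malformed %s value '%s'",
                   line_no[bad[1]], field, txt[bad[1]]))
    if (!allow_empty && any(empty))
      stop(sprintf("line %d: missing %s", line_no[which(empty)[1]], field))
    out
  }

  dates <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  if (anyNA(dates))
    stop(sprintf("line %d: malformed date '%s'",
                 line_no[which(is.na(dates))[1]], raw$date[which(is.na(dates))[1]]))
  pre <- parse_num(raw$pre_weight_kg, "pre_weight_kg", allow_empty = TRUE)
  post <- parse_num(raw$post_weight_kg, "post_weight_kg", allow_empty = TRUE)
  uf <- parse_num(raw$uf_ml, "uf_ml", allow_empty = FALSE)

  bad_uf <- which(uf < 0)
  if (length(bad_uf))
    stop(sprintf("line %d: negative uf_ml (%s)", line_no[bad_uf[1]],
                 raw$uf_ml[bad_uf[1]]))
  for (w in list(pre, post)) {
    bad_w <- which(!is.na(w) & (w <= 20 | w >= 200))
    if (length(bad_w))
      stop(sprintf("line %d: weight %s kg outside (20, 200)",
                   line_no[bad_w[1]], w[bad_w[1]]))
  }

  if (have_group) {
    grp <- ifelse(nzchar(raw$group), raw$group, "unknown")
    bad_g <- which(!grp %in% .hdw_groups)
    if (length(bad_g))
      stop(sprintf("line %d: unknown group '%s'", line_no[bad_g[1]],
                   grp[bad_g[1]]))
  } else {
    grp <- rep("unknown", n)
  }

  ids <- raw$patient_id
  if (any(!nzchar(ids)))
    stop(sprintf("line %d: empty patient_id", line_no[which(!nzchar(ids))[1]]))

  out <- list()
  for (id in unique(ids)) {
    sel <- ids == id
    if (anyDuplicated(dates[sel])) {
      dup <- dates[sel][duplicated(dates[sel])][1]
      stop(sprintf("duplicate session date %s for patient %s",
                   format(dup), id))
    }
    g <- unique(grp[sel])
    if (length(g) > 1)
      stop("inconsistent group labels for patient ", id)
    out[[id]] <- patient_series(id, dates[sel], pre[sel], post[sel], uf[sel],
                                group = g)
  }
  out
}

#' Write hemodialysis session records to CSV
#'
#' Serializes a list of [patient_series()] in the fixed schema used by
#' [read_hd_sessions()]. Weights and UF are written with 3 decimal places
#' (gram resolution) so that a read/write round trip is exact for values at
#' that resolution; missing weights become empty fields; a `group` column is
#' always written (`unknown` as empty).
#'
#' @param series_list A `patient_series` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hd_sessions <- function(series_list, path) {
  if (inherits(series_list, "patient_series")) series_list <- list(series_list)
  lapply(series_list, validate_patient_series)
  fmt_w <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))
  rows <- lapply(series_list, function(ps) {
    s <- ps$sessions
    data.frame(
      patient_id = rep(ps$patient_id, nrow(s)),
      date = format(s$date, "%Y-%m-%d"),
      pre_weight_kg = fmt_w(s$pre_weight),
      post_weight_kg = fmt_w(s$post_weight),
      uf_ml = sprintf("%.3f", s$uf_ml),
      group = rep(if (ps$group == "unknown") "" else ps$group, nrow(s))
    )
  })
  tab <- if (length(rows) == 0)
    data.frame(patient_id = character(0), date = character(0),
               pre_weight_kg = character(0), post_weight_kg = character(0),
               uf_ml = character(0), group = character(0))
  else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
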