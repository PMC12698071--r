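#' Attach Medicare fees to service records
#'
#' Prices each billed service line at the combined fee (MPFS + 106% ASP) in
#' effect in the calendar quarter of its service date, giving
#' `line_cost = units * unit_fee`.  Identical (patient, date, code) rows are
#' kept as separate billed lines; claims may legitimately repeat.
#'
#' @param services data.frame with columns `patient_id`, `service_date`
#'   (Date or ISO-8601 string), `code`, `units` (integer >= 1).
#' @param table A [fee_schedule()] object.
#' @param unresolved What to do with codes that cannot be priced for their
#'   quarter: `"fail"` (default) raises a lookup error, `"drop"` removes the
#'   lines with a warning, `"zero"` keeps them at zero cost with a warning.
#' @return The input data.frame with `unit_fee` and `line_cost` columns
#'   appended; attribute `"n_unresolved"` counts lines dropped or zeroed.
#' @export
cost_services <- function(services, table,
                          unresolved = c("fail", "drop", "zero")) {
  unresolved <- match.arg(unresolved)
  stopifnot(inherits(table, "fee_schedule"))
  services <- as.data.frame(services)
  need <- c("patient_id", "service_date", "code", "units")
  miss <- setdiff(need, names(services))
  if (length(miss))
    stop_input("services is missing column(s): ", paste(miss, collapse = ", "))

  if (nrow(services) == 0) {
    services$unit_fee <- numeric(0)
    services$line_cost <- numeric(0)
    attr(services, "n_unresolved") <- 0L
    return(services)
  }

  services$service_date <- as.Date(services$service_date)
  services$units <- as.integer(services$units)
  if (anyNA(services$units) || any(services$units < 1))
    stop_input("units must be integer >= 1 on every service line")

  yq <- quarter_of(services$service_date)
  key <- paste(services$code, yq$year, yq$quarter, sep = "|")
  idx <- match(key, table$key)

  if (anyNA(idx)) {
    n_bad <- sum(is.na(idx))
    if (unresolved == "fail") {
      bad <- which(is.na(idx))[1]
      if (!as.character(services$code[bad]) %in% table$entries$code)
        stop_input("service code never seen in fee schedule: ", services$code[bad])
      stop_input("service code ", services$code[bad],
                 " has no fee entry for ", yq$year[bad], " Q", yq$quarter[bad])
    }
    warning(n_bad, " service line(s) with unresolvable codes ",
            if (unresolved == "drop") "dropped" else "kept at zero cost",
            call. = FALSE)
    if (unresolved == "drop") {
      keep <- !is.na(idx)
      services <- services[keep, , drop = FALSE]
      idx <- idx[keep]
    }
  } else {
    n_bad <- 0L
  }

  fees <- entry_fees(table)[idx]
  fees[is.na(fees)] <- 0
  services$unit_fee <- fees
  services$line_cost <- services$units * fees
  attr(services, "n_unresolved") <- n_bad
  services
}

#' Daily cost series for one patient
#'
#' Bins priced service lines into calendar days of the therapy window.
#' Day 1 is the therapy start date and the window is days `1..window_days`
#' inclusive; services dated before day 1 or after the window are excluded
#' and counted in the `n_excluded` attribute.
#'
#' @param costed Output of [cost_services()] for one patient.
#' @param therapy_start Date of the first day of systemic therapy.
#' @param window_days Observation window length in days (default 180).
#' @return An object of class `patient_cost_series`: list with
#'   `patient_id`, `therapy_start`, `window_days` and `daily_cost`
#'   (numeric vector of length `window_days`).
#' @export
build_series <- function(costed, therapy_start, window_days = 180L) {
  window_days <- as.integer(window_days)
  if (window_days < 1) stop_input("window_days must be >= 1")
  therapy_start <- as.Date(therapy_start)
  costed <- as.data.frame(costed)

  pid <- if (nrow(costed)) as.character(costed$patient_id[1]) else NA_character_
  if (nrow(costed) && length(unique(costed$patient_id)) > 1)
    stop_input("build_series expects services for a single patient")

  daily <- numeric(window_days)
  n_excluded <- 0L
  if (nrow(costed)) {
    day <- as.integer(as.Date(costed$service_date) - therapy_start) + 1L
    inside <- day >= 1L & day <= window_days
    n_excluded <- sum(!inside)
    if (any(inside)) {
      s <- rowsum(costed$line_cost[inside], day[inside])
      daily[as.integer(rownames(s))] <- s[, 1]
    }
  }
  structure(
    list(patient_id = pid, therapy_start = therapy_start,
         window_days = window_days, daily_cost = daily),
    class = "patient_cost_series", n_excluded = n_excluded
  )
}

#' Cohort-wide daily cost matrix
#'
#' Vectorised equivalent of calling [build_series()] per patient: one row
#' per cohort patient, one column per therapy day.  Patients with no billed
#' services get an all-zero row.
#'
#' @param costed Output of [cost_services()] for the whole cohort.
#' @param cohort data.frame with `patient_id` and `therapy_start` columns.
#' @param window_days Observation window length in days (default 180).
#' @return An object of class `cohort_cost_matrix`: list with `patient_id`,
#'   `therapy_start`, `window_days` and `daily` (matrix, patients x days).
#'   Attribute `n_excluded` counts service lines outside the window.
#' @export
build_cost_matrix <- function(costed, cohort, window_days = 180L) {
  window_days <- as.integer(window_days)
  if (window_days < 1) stop_input("window_days must be >= 1")
  cohort <- as.data.frame(cohort)
  if (!all(c("patient_id", "therapy_start") %in% names(cohort)))
    stop_input("cohort must have patient_id and therapy_start columns")
  if (nrow(cohort) == 0) stop_input("no patients after validation")
  if (anyDuplicated(cohort$patient_id))
    stop_input("duplicate patient_id in cohort table")

  pid <- as.character(cohort$patient_id)
  start <- as.Date(cohort$therapy_start)
  n <- length(pid)
  m <- matrix(0, nrow = n, ncol = window_days,
              dimnames = list(pid, NULL))

  costed <- as.data.frame(costed)
  n_excluded <- 0L
  if (nrow(costed)) {
    pi <- match(as.character(costed$patient_id), pid)
    if (anyNA(pi))
      stop_input("service lines reference patient_id absent from cohort: ",
                 costed$patient_id[which(is.na(pi))[1]])
    day <- as.integer(as.Date(costed$service_date) - start[pi]) + 1L
    inside <- day >= 1L & day <= window_days
    n_excluded <- sum(!inside)
    if (any(inside)) {
      # column-major linear index of [patient, day]
      lin <- (day[inside] - 1L) * n + pi[inside]
      s <- rowsum(costed$line_cost[inside], lin)
      m[as.numeric(rownames(s))] <- s[, 1]
    }
  }
  structure(
    list(patient_id = pid, therapy_start = start,
         window_days = window_days, daily = m),
    class = "cohort_cost_matrix", n_excluded = n_excluded
  )
}

#' Total cost per patient per period (TCPP)
#'
#' Sum of daily costs over the observation window.
#'
#' @param series A `patient_cost_series` or `cohort_cost_matrix`.
#' @return Scalar (single series) or named vector (cohort) in USD.
#' @export
tcpp <- function(series) UseMethod("tcpp")

#' @export
tcpp.patient_cost_series <- function(series) sum(series$daily_cost)

#' @export
tcpp.cohort_cost_matrix <- function(series) rowSums(series$daily)

#' Cost of care per patient per day (CCPD)
#'
#' TCPP divided by the observation-window length, i.e. the average daily
#' cost over the full window (distinct from raw single-day totals).
#'
#' @inheritParams tcpp
#' @return Scalar or named vector in USD/day.
#' @export
ccpd <- function(series) UseMethod("ccpd")

#' @export
ccpd.patient_cost_series <- function(series) tcpp(series) / series$window_days

#' @export
ccpd.cohort_cost_matrix <- function(series) tcpp(series) / series$window_days

#' Cumulative cost curve
#'
#' Running sum of daily costs; the final element equals [tcpp()] and the
#' curve is monotone non-decreasing.
#'
#' @inheritParams tcpp
#' @return Numeric vector (single series) or matrix (cohort, patients x days).
#' @export
cumulative_curve <- function(series) UseMethod("cumulative_curve")

#' @export
cumulative_curve.patient_cost_series <- function(series) cumsum(series$daily_cost)

#' @export
cumulative_curve.cohort_cost_matrix <- function(series) {
  m <- series$daily
  if (ncol(m) > 1)
    for (j in 2:ncol(m)) m[, j] <- m[, j - 1] + m[, j]
  m
}

#' @export
print.patient_cost_series <- function(x, ...) {
  cat("<patient_cost_series> patient", x$patient_id,
      "| window", x$window_days, "days",
      "| TCPP", sprintf("%.2f", round_cents(tcpp(x))),
      "| CCPD", sprintf("%.2f", round_cents(ccpd(x))), "\n")
  invisible(x)
}

#' @export
print.cohort_cost_matrix <- function(x, ...) {
  cat("<cohort_cost_matrix>", length(x$patient_id), "patients x",
      x$window_days, "days; mean TCPP",
      sprintf("%.2f", round_cents(mean(tcpp(x)))), "\n")
  invisible(x)
}

#' Per-patient cost table
#'
#' @param cm A `cohort_cost_matrix`.
#' @return data.frame with `patient_id`, `tcpp`, `ccpd` (rounded to cents).
#' @export
patient_cost_table <- function(cm) {
  stopifnot(inherits(cm, "cohort_cost_matrix"))
  data.frame(patient_id = cm$patient_id,
             tcpp = round_cents(tcpp(cm)),
             ccpd = round_cents(ccpd(cm)),
             row.names = NULL)
}
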