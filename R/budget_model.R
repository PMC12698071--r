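#' Budget-impact model parameters
#'
#' All inputs of the two cost equations comparing usual care (no prediction
#' model) with deployment of an ACU risk-prediction model, plus the model's
#' operating characteristics.  Defaults are the base-case scenario: an
#' annual cohort of 2177 systemic-therapy patients with 18.58% ACU
#' prevalence, a LASSO risk model with sensitivity 0.84 and specificity
#' 0.51, a 35% prevention rate among correctly flagged patients, a mean
#' ACU cost of $17,031.92, $1M one-time deployment, $200K/yr maintenance,
#' and $112,765/yr combined nurse (0.25 FTE) + advanced practice provider
#' (0.5 FTE) staffing.
#'
#' @param n_total Patients entering systemic therapy per year.
#' @param p_prev Baseline ACU prevalence, in `[0, 1]`.
#' @param r_sens,r_spec Sensitivity and specificity of the risk model.
#' @param p_pred Proportion of correctly flagged ACU events assumed
#'   preventable (prevention rate).
#' @param c_acu Mean 180-day cost per ACU patient, USD.
#' @param c_deploy One-time deployment cost, USD.
#' @param c_annual Annual maintenance cost from year 2 on, USD.
#' @param c_nurse,c_app Annual nurse / advanced-practice-provider staffing
#'   costs, USD.  Only their sum enters the cost equations; the default
#'   split assigns the combined $112,765 as 1/3 nurse (0.25 FTE) to 2/3
#'   APP (0.5 FTE).
#' @param c_fp Marginal cost per false-positive flag per year, USD
#'   (default 0: alert triage labour is inside the fixed staffing FTEs).
#' @return Object of class `budget_params`.
#' @export
budget_params <- function(n_total = 2177,
                          p_prev = 0.1858,
                          r_sens = 0.84,
                          r_spec = 0.51,
                          p_pred = 0.35,
                          c_acu = 17031.92,
                          c_deploy = 1e6,
                          c_annual = 2e5,
                          c_nurse = 112765 / 3,
                          c_app = 2 * 112765 / 3,
                          c_fp = 0) {
  p <- list(n_total = n_total, p_prev = p_prev, r_sens = r_sens,
            r_spec = r_spec, p_pred = p_pred, c_acu = c_acu,
            c_deploy = c_deploy, c_annual = c_annual,
            c_nurse = c_nurse, c_app = c_app, c_fp = c_fp)
  for (nm in c("p_prev", "r_sens", "r_spec", "p_pred"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop_input(nm, " must lie in [0, 1]")
  for (nm in c("c_acu", "c_deploy", "c_annual", "c_nurse", "c_app", "c_fp"))
    if (p[[nm]] < 0) stop_input(nm, " must be >= 0")
  if (p$n_total < 1) stop_input("n_total must be >= 1")
  structure(p, class = "budget_params")
}

#' @export
print.budget_params <- function(x, ...) {
  cat("<budget_params>\n")
  cat(sprintf("  cohort: n_total = %g/yr, p_prev = %.4f\n", x$n_total, x$p_prev))
  cat(sprintf("  model:  sens = %.2f, spec = %.2f, prevention rate = %.2f\n",
              x$r_sens, x$r_spec, x$p_pred))
  cat(sprintf("  costs:  C_acu = %.2f, deploy = %.0f, maintenance = %.0f/yr, staffing = %.0f/yr\n",
              x$c_acu, x$c_deploy, x$c_annual, x$c_nurse + x$c_app))
  invisible(x)
}

#' Expected yearly ACU events without intervention
#'
#' `N_acu0 = n_total * p_prev` (fractional; the expectation is not rounded).
#'
#' @param p A [budget_params()] object.
#' @return Expected events per year.
#' @export
expected_acu_events <- function(p) {
  stopifnot(inherits(p, "budget_params"))
  p$n_total * p$p_prev
}

#' Yearly true-positive flags of the risk model
#'
#' Whole patients correctly flagged as high risk:
#' `floor(expected_acu_events * r_sens)`.
#'
#' @inheritParams expected_acu_events
#' @return Integer count per year.
#' @export
flagged_true_positives <- function(p) {
  stopifnot(inherits(p, "budget_params"))
  as.integer(floor_tol(expected_acu_events(p) * p$r_sens))
}

#' Yearly false-positive flags of the risk model
#'
#' Patients not at risk who are incorrectly flagged:
#' `n_total * (1 - p_prev) * (1 - r_spec)` (fractional expectation).
#'
#' @inheritParams expected_acu_events
#' @return Expected count per year.
#' @export
false_positive_count <- function(p) {
  stopifnot(inherits(p, "budget_params"))
  p$n_total * (1 - p$p_prev) * (1 - p$r_spec)
}

#' Yearly prevented ACU events
#'
#' Prevention acts on correctly flagged patients:
#' `round(flagged_true_positives * p_pred)`, half up to whole events.
#'
#' @inheritParams expected_acu_events
#' @return Integer count per year.
#' @export
prevented_events <- function(p) {
  stopifnot(inherits(p, "budget_params"))
  as.integer(round_half_up(flagged_true_positives(p) * p$p_pred))
}

#' Cumulative cost of usual care over x years (C0)
#'
#' `C0(x) = c_acu * N_acu0 * x`: every expected ACU event accrues the mean
#' per-event cost, with no model costs.
#'
#' @inheritParams expected_acu_events
#' @param x Years since deployment would have happened (>= 0).
#' @return Cost in USD.
#' @export
cost_without_model <- function(p, x) {
  stopifnot(inherits(p, "budget_params"))
  if (any(x < 0)) stop_input("x must be >= 0")
  p$c_acu * expected_acu_events(p) * x
}

#' Cumulative cost with the deployed model over x years (C1)
#'
#' `C1(x) = c_deploy + c_annual*(x-1) + c_acu1*x + c_nurse*x + c_app*x`,
#' where the residual yearly ACU cost is
#' `c_acu1 = c_acu * (N_acu0 - prevented_events)`.  An optional
#' false-positive cost `c_fp * false_positive_count * x` is added when
#' `c_fp > 0`.
#'
#' @inheritParams expected_acu_events
#' @param x Years since deployment (>= 1; the model must be deployed).
#' @return Cost in USD.
#' @export
cost_with_model <- function(p, x) {
  stopifnot(inherits(p, "budget_params"))
  if (any(x < 1)) stop_input("x must be >= 1 (model deployed in year 1)")
  c_acu1 <- p$c_acu * (expected_acu_events(p) - prevented_events(p))
  p$c_deploy + p$c_annual * (x - 1) + c_acu1 * x +
    (p$c_nurse + p$c_app) * x + p$c_fp * false_positive_count(p) * x
}

#' Multi-year budget-impact projection
#'
#' Year-by-year comparison of the two cost equations.  Per year `y`:
#' `cumulative_savings(y) = C0(y) - C1(y)`, `savings(y)` its yearly
#' increment, and `roi(y)` the cumulative savings divided by the cumulative
#' implementation cost (deployment + maintenance + staffing to date).
#'
#' @inheritParams expected_acu_events
#' @param horizon Projection length in years (>= 1).
#' @return data.frame of class `budget_projection` with columns `year`,
#'   `c0`, `c1`, `savings`, `cumulative_savings`, `roi`.
#' @export
projection <- function(p, horizon = 6L) {
  stopifnot(inherits(p, "budget_params"))
  horizon <- as.integer(horizon)
  if (horizon < 1) stop_input("horizon must be >= 1")
  years <- seq_len(horizon)
  c0 <- cost_without_model(p, years)
  c1 <- cost_with_model(p, years)
  cum <- c0 - c1
  sav <- diff(c(0, cum))
  impl <- p$c_deploy + p$c_annual * (years - 1) + (p$c_nurse + p$c_app) * years
  out <- data.frame(year = years, c0 = c0, c1 = c1, savings = sav,
                    cumulative_savings = cum, roi = cum / impl)
  class(out) <- c("budget_projection", "data.frame")
  out
}

#' @export
print.budget_projection <- function(x, ...) {
  df <- as.data.frame(x)
  for (col in c("c0", "c1", "savings", "cumulative_savings"))
    df[[col]] <- round_cents(df[[col]])
  df$roi <- round(df$roi, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Headline savings at reporting granularity
#'
#' Rounds a savings figure to the nearest `unit` dollars (default $10,000),
#' the granularity used for headline results; raw values are kept in the
#' projection table.
#'
#' @param x Savings in USD.
#' @param unit Rounding unit in USD.
#' @return Rounded USD value.
#' @export
headline_savings <- function(x, unit = 1e4) round_to_unit(x, unit)
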