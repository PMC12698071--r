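# Deterministic one-way (break-even) sensitivity analysis of the budget
# model: which values of r_sens, p_prev, n_total, p_pred make cumulative
# savings at a horizon cross zero.

sweepable_params <- c("r_sens", "p_prev", "n_total", "p_pred")

set_param <- function(base, parameter, value) {
  args <- unclass(base)
  args[[parameter]] <- value
  do.call(budget_params, args)
}

#' Cumulative savings at a horizon
#'
#' `C0(horizon) - C1(horizon)`.  With `continuous = TRUE` the integer
#' rounding of flagged and prevented events is relaxed
#' (`prevented = n_total * p_prev * r_sens * p_pred`), giving the smooth
#' function used for root finding; the default reproduces [projection()].
#'
#' @param p A [budget_params()] object.
#' @param horizon Years (>= 1).
#' @param continuous Relax the integer event-rounding chain.
#' @return Savings in USD (negative = net cost).
#' @export
cumulative_savings <- function(p, horizon = 6L, continuous = FALSE) {
  stopifnot(inherits(p, "budget_params"))
  if (horizon < 1) stop_input("horizon must be >= 1")
  prev <- if (continuous) {
    expected_acu_events(p) * p$r_sens * p$p_pred
  } else {
    prevented_events(p)
  }
  p$c_acu * prev * horizon -
    p$c_deploy - p$c_annual * (horizon - 1) -
    (p$c_nurse + p$c_app) * horizon -
    p$c_fp * false_positive_count(p) * horizon
}

#' One-way parameter sweep of cumulative savings
#'
#' Varies one parameter over a grid while holding the others at their base
#' values, recording cumulative savings at the horizon for each grid point
#' (integer-rounded model, identical to [projection()]).
#'
#' @param base A [budget_params()] object.
#' @param parameter One of `"r_sens"`, `"p_prev"`, `"n_total"`, `"p_pred"`.
#' @param grid Ordered numeric vector of parameter values within the
#'   parameter's valid range.
#' @param horizon Years (>= 1).
#' @return Object of class `sensitivity_result`: list with `parameter`,
#'   `horizon`, `grid` (data.frame `value`, `cumulative_savings`) and
#'   `break_even_value` (smallest grid value with savings >= 0, or `NA`).
#' @export
one_way_sweep <- function(base, parameter, grid, horizon = 6L) {
  stopifnot(inherits(base, "budget_params"))
  parameter <- match.arg(parameter, sweepable_params)
  if (is.unsorted(grid)) stop_input("grid must be ordered increasing")
  cs <- vapply(grid, function(v)
    cumulative_savings(set_param(base, parameter, v), horizon), numeric(1))
  hit <- which(cs >= 0)
  structure(
    list(parameter = parameter, horizon = horizon,
         grid = data.frame(value = grid, cumulative_savings = cs),
         break_even_value = if (length(hit)) grid[hit[1]] else NA_real_),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> parameter", x$parameter,
      "| horizon", x$horizon, "years |",
      nrow(x$grid), "grid points | break-even at",
      if (is.na(x$break_even_value)) "none in range"
      else format(x$break_even_value), "\n")
  invisible(x)
}

#' Break-even threshold of a budget-model parameter
#'
#' Smallest value of the parameter (others held at base values) for which
#' cumulative savings at the horizon reach zero, found by bisection on the
#' continuous relaxation of the savings function (savings are monotone
#' increasing in each supported parameter).  The integer-rounded model can
#' step across zero up to one event earlier or later; report it alongside
#' via [one_way_sweep()].
#'
#' @inheritParams one_way_sweep
#' @param range Search interval; defaults to the parameter's valid range
#'   (`[0, 1]` for probabilities, `[1, 100 * base]` for `n_total`).
#' @param tol Bisection tolerance on the parameter value.
#' @return The threshold value, or `NA` with attribute
#'   `status = "no break-even in range"` when savings never reach zero.
#' @export
break_even_threshold <- function(base, parameter, horizon = 6L,
                                 range = NULL, tol = 1e-8) {
  stopifnot(inherits(base, "budget_params"))
  parameter <- match.arg(parameter, sweepable_params)
  if (is.null(range)) {
    range <- if (parameter == "n_total") c(1, 100 * base$n_total) else c(0, 1)
  }
  f <- function(v) cumulative_savings(set_param(base, parameter, v),
                                      horizon, continuous = TRUE)
  lo <- range[1]; hi <- range[2]
  if (f(lo) >= 0) return(lo)
  if (f(hi) < 0)
    return(structure(NA_real_, status = "no break-even in range"))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  hi
}

#' First year of non-negative cumulative savings
#'
#' @param base A [budget_params()] object.
#' @param max_horizon Latest year scanned (>= 1).
#' @return The first year whose cumulative savings are >= 0, or `NA` if no
#'   year up to `max_horizon` breaks even.
#' @export
break_even_year <- function(base, max_horizon = 10L) {
  stopifnot(inherits(base, "budget_params"))
  max_horizon <- as.integer(max_horizon)
  if (max_horizon < 1) stop_input("max_horizon must be >= 1")
  proj <- projection(base, max_horizon)
  hit <- which(proj$cumulative_savings >= 0)
  if (length(hit)) proj$year[hit[1]] else NA_integer_
}

#' Break-even thresholds for all sweepable parameters
#'
#' @inheritParams break_even_threshold
#' @param horizons Years at which to evaluate thresholds.
#' @return data.frame with `parameter`, `horizon`, `threshold` (NA when no
#'   break-even exists in the parameter's range).
#' @export
break_even_table <- function(base, horizons = c(1L, 6L)) {
  out <- expand.grid(parameter = sweepable_params, horizon = horizons,
                     stringsAsFactors = FALSE)
  out$threshold <- mapply(function(pm, h) {
    as.numeric(break_even_threshold(base, pm, horizon = h))
  }, out$parameter, out$horizon)
  out
}
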