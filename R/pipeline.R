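#' Read a pipeline run configuration
#'
#' Reads a YAML or JSON config (by file extension) describing either input
#' CSV paths (`inputs:` with `fee_schedule`, `gpci`, `cf`, `services`,
#' `cohort`, and optionally `flags`) or a synthetic-data block
#' (`synthetic:` with [synthetic_config()] fields) — exactly one of the
#' two — plus optional `budget:` ([budget_params()] fields), `horizon`,
#' `window_days`, `checkpoints` and `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_input("config must be a .yaml/.yml or .json file: ", path)
  }
  as_run_config(cfg)
}

#' Validate a run configuration list
#'
#' @param cfg Named list with the fields described in [read_run_config()].
#' @return The list with class `run_config`.
#' @export
as_run_config <- function(cfg) {
  has_inputs <- !is.null(cfg$inputs)
  has_synth <- !is.null(cfg$synthetic)
  if (has_inputs == has_synth)
    stop_input("config must provide exactly one of 'inputs' or 'synthetic'")
  cfg$horizon <- as.integer(cfg$horizon %||% 6L)
  cfg$window_days <- as.integer(cfg$window_days %||% 180L)
  cfg$checkpoints <- as.integer(cfg$checkpoints %||% c(30L, 90L, 180L))
  structure(cfg, class = "run_config")
}

# Load (or generate) the study tables a run needs.
load_study <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    sc <- do.call(synthetic_config, cfg$synthetic)
    gen_synthetic_study(sc)
  } else {
    ip <- cfg$inputs
    for (nm in c("fee_schedule", "gpci", "cf", "services", "cohort"))
      if (is.null(ip[[nm]])) stop_input("inputs block is missing '", nm, "'")
    table <- parse_fee_schedule(ip$fee_schedule, ip$gpci, ip$cf)
    services <- utils::read.csv(ip$services, stringsAsFactors = FALSE,
                                colClasses = c(code = "character",
                                               patient_id = "character"))
    cohort <- utils::read.csv(ip$cohort, stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
    flags <- if (!is.null(ip$flags)) {
      utils::read.csv(ip$flags, stringsAsFactors = FALSE,
                      colClasses = c(patient_id = "character"))
    }
    list(table = table, cohort = cohort, services = services, flags = flags)
  }
}

#' Run the cohort cost analysis
#'
#' End-to-end cost arm of the pipeline: price services, accrue daily costs
#' over the therapy window, and compare ACU vs non-ACU groups.  When `out`
#' is given, writes `patient_costs.csv`, `group_summaries.csv`,
#' `tests.csv` and `cumulative_curves.csv` (long format: group, day, mean
#' cumulative cost).
#'
#' @param cfg A `run_config` (see [read_run_config()]), or a list coercible
#'   by [as_run_config()].
#' @param out Optional output directory.
#' @return List of class `cost_report`: `patient_costs`, `summaries`,
#'   `tests`, `curves`, `cost_matrix`, `cohort`, and exclusion counts.
#' @export
run_cost_analysis <- function(cfg, out = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- as_run_config(cfg)
  study <- load_study(cfg)
  cohort <- study$cohort
  if (is.null(cohort) || nrow(cohort) == 0)
    stop_input("no patients after validation")
  if (!"acu_flag" %in% names(cohort))
    stop_input("cohort table must have an acu_flag column")

  costed <- cost_services(study$services, study$table)
  cm <- build_cost_matrix(costed, cohort, cfg$window_days)
  comp <- compare_groups(cm, cohort$acu_flag, cfg$checkpoints)
  pct <- patient_cost_table(cm)

  cum <- cumulative_curve(cm)
  acu <- as.logical(cohort$acu_flag)
  curves <- rbind(
    data.frame(group = "acu", day = seq_len(cfg$window_days),
               mean_cum_cost = round_cents(colMeans(cum[acu, , drop = FALSE]))),
    data.frame(group = "non_acu", day = seq_len(cfg$window_days),
               mean_cum_cost = round_cents(colMeans(cum[!acu, , drop = FALSE])))
  )

  report <- list(patient_costs = pct, summaries = comp$summaries,
                 tests = comp$tests, curves = curves,
                 cost_matrix = cm, cohort = cohort,
                 n_excluded_services = attr(cm, "n_excluded"),
                 n_unresolved_services = attr(costed, "n_unresolved"))
  class(report) <- "cost_report"
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pct, file.path(out, "patient_costs.csv"), row.names = FALSE)
    utils::write.csv(comp$summaries, file.path(out, "group_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(comp$tests, file.path(out, "tests.csv"), row.names = FALSE)
    utils::write.csv(curves, file.path(out, "cumulative_curves.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.cost_report <- function(x, ...) {
  cat("<cost_report>", nrow(x$patient_costs), "patients;",
      x$n_excluded_services, "service line(s) outside window\n")
  print(x$summaries)
  invisible(x)
}

#' Run the cost-benefit (budget-impact) analysis
#'
#' Builds [budget_params()] from the config's `budget:` block; fields not
#' given there can be estimated from a [run_cost_analysis()] report
#' (`p_prev` as the cohort ACU share, `c_acu` as the ACU-group mean TCPP).
#' Produces the multi-year projection, break-even thresholds, and one-way
#' sweeps for every sweepable parameter.  When `out` is given, writes
#' `projection.csv`, `thresholds.json` and `sensitivity_<parameter>.csv`.
#'
#' @param cfg A `run_config` or coercible list.
#' @param cost_report Optional `cost_report` supplying estimated
#'   `p_prev`/`c_acu` when the budget block omits them.
#' @param out Optional output directory.
#' @return List of class `cba_report`: `params`, `projection`,
#'   `thresholds`, `sweeps`, `headline` (year-1 and horizon savings, raw
#'   and rounded to $10,000).
#' @export
run_cba <- function(cfg, cost_report = NULL, out = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- as_run_config(cfg)
  if (cfg$horizon < 1) stop_input("horizon must be >= 1")
  budget <- cfg$budget %||% list()
  if (!is.null(cost_report)) {
    if (is.null(budget$p_prev))
      budget$p_prev <- mean(as.logical(cost_report$cohort$acu_flag))
    if (is.null(budget$c_acu)) {
      s <- cost_report$summaries
      budget$c_acu <- s$mean[s$group == "acu" & s$measure == "tcpp"]
    }
    if (is.null(budget$n_total))
      budget$n_total <- nrow(cost_report$cohort)
  }
  params <- do.call(budget_params, budget)

  proj <- projection(params, cfg$horizon)
  thresholds <- break_even_table(params, horizons = c(1L, cfg$horizon))
  sweeps <- lapply(stats::setNames(sweepable_params, sweepable_params),
                   function(pm) {
    grid <- if (pm == "n_total") {
      seq(1, 2 * params$n_total, length.out = 50)
    } else {
      seq(0, 1, length.out = 50)
    }
    one_way_sweep(params, pm, grid, cfg$horizon)
  })

  headline <- list(
    year1_savings = proj$savings[1],
    year1_savings_rounded = headline_savings(proj$savings[1]),
    horizon = cfg$horizon,
    horizon_cumulative_savings = proj$cumulative_savings[cfg$horizon],
    horizon_cumulative_savings_rounded =
      headline_savings(proj$cumulative_savings[cfg$horizon]),
    break_even_year = break_even_year(params, cfg$horizon)
  )

  report <- list(params = params, projection = proj, thresholds = thresholds,
                 sweeps = sweeps, headline = headline)
  class(report) <- "cba_report"
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(proj), file.path(out, "projection.csv"),
                     row.names = FALSE)
    th <- split(thresholds[c("horizon", "threshold")], thresholds$parameter)
    jsonlite::write_json(th, file.path(out, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    for (pm in names(sweeps))
      utils::write.csv(sweeps[[pm]]$grid,
                       file.path(out, paste0("sensitivity_", pm, ".csv")),
                       row.names = FALSE)
  }
  report
}

#' @export
print.cba_report <- function(x, ...) {
  h <- x$headline
  cat("<cba_report> horizon", h$horizon, "years\n")
  cat(sprintf("  year-1 savings: %.2f (~%s at $10K granularity)\n",
              h$year1_savings, format(h$year1_savings_rounded, big.mark = ",")))
  cat(sprintf("  cumulative savings at year %d: %.2f (~%s)\n",
              h$horizon, h$horizon_cumulative_savings,
              format(h$horizon_cumulative_savings_rounded, big.mark = ",")))
  cat("  break-even year:", h$break_even_year, "\n")
  invisible(x)
}
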