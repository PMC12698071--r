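#' Configuration for the synthetic claims-data generator
#'
#' Defines the study conditions the generator emulates: a two-group
#' oncology cohort (ACU vs non-ACU) whose 180-day cost accrual matches the
#' target group means/SDs, billed as service lines priced against a
#' generated quarterly fee schedule, plus risk flags with stated operating
#' characteristics.  Defaults are the base-case cohort: 18.58% ACU
#' prevalence, target TCPPs $17,031.92 (SD $13,056.63) vs $9,591.06
#' (SD $10,785.83), and a risk model at sensitivity 0.84 / specificity
#' 0.51.
#'
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param n_patients Cohort size.
#' @param p_prev ACU prevalence.
#' @param target_tcpp_acu,target_tcpp_nonacu Target group mean 180-day
#'   total costs (USD, > 0).
#' @param target_sd_acu,target_sd_nonacu Target group SDs (USD, > 0).
#' @param window_days Observation window (days).
#' @param n_codes Number of HCPCS-like codes in the fee schedule.
#' @param drug_fraction Fraction of codes that carry an ASP drug price.
#' @param r_sens,r_spec Operating characteristics of the risk flags.
#' @param start_year Calendar year in which therapy starts are drawn.
#' @param decay_tau Time constant (days) of the exponential-decay daily
#'   cost profile (high day-1 cost, flattening later).
#' @param episode_frac Fraction of an ACU patient's total cost placed in a
#'   boxcar acute-care episode burst.
#' @param episode_len Length (days) of the episode burst.
#' @param feature_spec Named list of categorical features; each element is
#'   a list with `categories`, `p_acu`, `p_nonacu` (probability vectors
#'   conditional on ACU status).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_patients = 20000L,
                             p_prev = 0.1858,
                             target_tcpp_acu = 17031.92,
                             target_tcpp_nonacu = 9591.06,
                             target_sd_acu = 13056.63,
                             target_sd_nonacu = 10785.83,
                             window_days = 180L,
                             n_codes = 120L,
                             drug_fraction = 0.2,
                             r_sens = 0.84,
                             r_spec = 0.51,
                             start_year = 2020L,
                             decay_tau = 60,
                             episode_frac = 0.35,
                             episode_len = 7L,
                             feature_spec = default_feature_spec()) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              p_prev = p_prev,
              target_tcpp_acu = target_tcpp_acu,
              target_tcpp_nonacu = target_tcpp_nonacu,
              target_sd_acu = target_sd_acu,
              target_sd_nonacu = target_sd_nonacu,
              window_days = as.integer(window_days),
              n_codes = as.integer(n_codes),
              drug_fraction = drug_fraction,
              r_sens = r_sens, r_spec = r_spec,
              start_year = as.integer(start_year),
              decay_tau = decay_tau,
              episode_frac = episode_frac,
              episode_len = as.integer(episode_len),
              feature_spec = feature_spec)
  for (nm in c("p_prev", "drug_fraction", "r_sens", "r_spec", "episode_frac"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop_input(nm, " must lie in [0, 1]")
  for (nm in c("target_tcpp_acu", "target_tcpp_nonacu",
               "target_sd_acu", "target_sd_nonacu"))
    if (cfg[[nm]] <= 0)
      stop_input("infeasible cost target: ", nm, " must be > 0")
  if (cfg$n_patients < 1) stop_input("n_patients must be >= 1")
  if (cfg$n_codes < 1) stop_input("n_codes must be >= 1")
  if (cfg$window_days < 1) stop_input("window_days must be >= 1")
  structure(cfg, class = "synthetic_config")
}

#' Default categorical feature specification
#'
#' Three features sampled conditional on ACU status, with the directions
#' seen in oncology cohorts: ACU patients skew toward advanced tumour
#' stage, non-breast tumour types, and Medicaid coverage, so chi-square
#' comparisons on the synthetic cohort carry real signal.
#'
#' @return Named list usable as `feature_spec` in [synthetic_config()].
#' @export
default_feature_spec <- function() {
  list(
    stage = list(
      categories = c("1", "2", "3", "4"),
      p_nonacu = c(0.30, 0.30, 0.25, 0.15),
      p_acu = c(0.15, 0.25, 0.25, 0.35)
    ),
    tumor_type = list(
      categories = c("breast", "gi", "gu", "lung", "other"),
      p_nonacu = c(0.35, 0.20, 0.10, 0.15, 0.20),
      p_acu = c(0.18, 0.22, 0.20, 0.20, 0.20)
    ),
    insurance = list(
      categories = c("medicare", "commercial", "medicaid"),
      p_nonacu = c(0.45, 0.45, 0.10),
      p_acu = c(0.45, 0.35, 0.20)
    )
  )
}

# lognormal parameters matching a target mean and sd by moments
lognormal_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic quarterly fee schedule
#'
#' Codes get lognormal RVU components; a `drug_fraction` subset carries an
#' ASP price with mild quarterly drift.  GPCI multipliers sit near 1 and
#' the conversion factor near the recent MPFS range.  Covers `start_year`
#' and the following year so 180-day windows starting late in the year
#' remain priceable.  Deterministic given the RNG state; call under
#' `set.seed()` (as [gen_synthetic_study()] does) for reproducibility.
#'
#' @param cfg A [synthetic_config()].
#' @return A [fee_schedule()] object.
#' @export
gen_fee_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_drug <- as.integer(round(cfg$n_codes * cfg$drug_fraction))
  n_proc <- cfg$n_codes - n_drug
  codes <- c(if (n_proc > 0) sprintf("P%04d", seq_len(n_proc)),
             if (n_drug > 0) sprintf("J%04d", seq_len(n_drug)))
  is_drug <- c(rep(FALSE, n_proc), rep(TRUE, n_drug))
  years <- cfg$start_year + 0:1

  work <- stats::rlnorm(cfg$n_codes, meanlog = log(0.9), sdlog = 0.6)
  pe <- stats::rlnorm(cfg$n_codes, meanlog = log(0.8), sdlog = 0.6)
  mp <- stats::rlnorm(cfg$n_codes, meanlog = log(0.08), sdlog = 0.5)
  asp_base <- ifelse(is_drug,
                     stats::rlnorm(cfg$n_codes, meanlog = log(150), sdlog = 0.9),
                     NA_real_)

  entries <- vector("list", length(years) * 4L)
  k <- 0L
  asp_now <- asp_base
  for (y in years) {
    # RVUs are annual; small year-over-year revision
    if (y != years[1]) {
      work <- work * stats::rlnorm(cfg$n_codes, 0, 0.02)
      pe <- pe * stats::rlnorm(cfg$n_codes, 0, 0.02)
      mp <- mp * stats::rlnorm(cfg$n_codes, 0, 0.02)
    }
    for (q in 1:4) {
      asp_now <- asp_now * stats::rlnorm(cfg$n_codes, 0, 0.02)  # quarterly drift
      k <- k + 1L
      entries[[k]] <- data.frame(
        code = codes, year = y, quarter = q,
        work_rvu = work, pe_rvu = pe, mp_rvu = mp,
        asp_price = asp_now
      )
    }
  }
  gpci <- data.frame(year = years,
                     work_gpci = 1 + stats::runif(length(years), -0.05, 0.05),
                     pe_gpci = 1 + stats::runif(length(years), -0.08, 0.08),
                     mp_gpci = 1 + stats::runif(length(years), -0.10, 0.10))
  cf <- data.frame(year = years,
                   cf = 34.6062 * (1 + 0.01 * (seq_along(years) - 1)))
  fee_schedule(do.call(rbind, entries), gpci, cf)
}

#' Generate a synthetic two-group cohort with service streams
#'
#' Each patient is labelled ACU with probability `p_prev` and given a
#' target 180-day total cost drawn from a lognormal moment-matched to the
#' group's target mean/SD (costs are positive and right-skewed).  The
#' total is spread over the window as an exponential-decay daily profile
#' (front-loaded therapy costs that flatten); ACU patients divert
#' `episode_frac` of their total into a boxcar acute-care burst starting
#' at a random day.  Daily targets are then realised as integer-unit
#' service lines priced against `table`, using stochastic rounding of
#' units so realised costs are unbiased for the targets.  Categorical
#' features are sampled conditional on ACU status per
#' `cfg$feature_spec`.
#'
#' @param cfg A [synthetic_config()].
#' @param table Fee schedule to bill against (from [gen_fee_schedule()]).
#' @return List with `cohort` (data.frame: `patient_id`, `therapy_start`,
#'   `acu_flag`, feature columns) and `services` (data.frame:
#'   `patient_id`, `service_date`, `code`, `units`).
#' @export
gen_cohort <- function(cfg, table) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(table, "fee_schedule"))
  n <- cfg$n_patients
  wd <- cfg$window_days
  pid <- sprintf("PT%06d", seq_len(n))

  start <- as.Date(sprintf("%d-01-01", cfg$start_year)) +
    sample.int(365L, n, replace = TRUE) - 1L
  acu <- stats::rbinom(n, 1L, cfg$p_prev) == 1L

  lp_a <- lognormal_params(cfg$target_tcpp_acu, cfg$target_sd_acu)
  lp_n <- lognormal_params(cfg$target_tcpp_nonacu, cfg$target_sd_nonacu)
  total <- numeric(n)
  total[acu] <- stats::rlnorm(sum(acu), lp_a$meanlog, lp_a$sdlog)
  total[!acu] <- stats::rlnorm(sum(!acu), lp_n$meanlog, lp_n$sdlog)

  # daily target costs: decay profile + episode burst for ACU patients
  decay <- exp(-(seq_len(wd) - 1) / cfg$decay_tau)
  decay <- decay / sum(decay)
  frac <- ifelse(acu, cfg$episode_frac, 0)
  daily <- outer(total * (1 - frac), decay)  # n x wd

  if (any(acu) && cfg$episode_frac > 0) {
    ep_max_start <- max(1L, wd - cfg$episode_len + 1L)
    ep_start <- integer(n)
    ep_start[acu] <- sample.int(ep_max_start, sum(acu), replace = TRUE)
    idx_acu <- which(acu)
    per_day <- total[idx_acu] * cfg$episode_frac / cfg$episode_len
    for (off in seq_len(cfg$episode_len) - 1L) {
      d <- pmin(ep_start[idx_acu] + off, wd)
      daily[cbind(idx_acu, d)] <- daily[cbind(idx_acu, d)] + per_day
    }
  }

  # realise targets as priced integer-unit service lines
  fees <- entry_fees(table)
  long_i <- rep(seq_len(n), times = wd)
  long_d <- rep(seq_len(wd), each = n)
  target <- as.vector(daily)
  code_row <- sample.int(length(unique(table$entries$code)), length(target),
                         replace = TRUE)
  codes <- unique(table$entries$code)[code_row]
  dates <- start[long_i] + long_d - 1L
  yq <- quarter_of(dates)
  key <- paste(codes, yq$year, yq$quarter, sep = "|")
  fee <- fees[match(key, table$key)]
  units <- floor(target / fee + stats::runif(length(target)))
  keep <- units >= 1
  services <- data.frame(
    patient_id = pid[long_i[keep]],
    service_date = dates[keep],
    code = codes[keep],
    units = as.integer(units[keep])
  )
  services <- services[order(services$patient_id, services$service_date,
                             services$code), , drop = FALSE]
  row.names(services) <- NULL

  cohort <- data.frame(patient_id = pid, therapy_start = start,
                       acu_flag = as.integer(acu))
  for (fname in names(cfg$feature_spec)) {
    fs <- cfg$feature_spec[[fname]]
    val <- character(n)
    if (any(acu))
      val[acu] <- sample(fs$categories, sum(acu), replace = TRUE, prob = fs$p_acu)
    if (any(!acu))
      val[!acu] <- sample(fs$categories, sum(!acu), replace = TRUE, prob = fs$p_nonacu)
    cohort[[fname]] <- val
  }
  list(cohort = cohort, services = services)
}

#' Generate risk flags with given operating characteristics
#'
#' Flags are drawn independently per patient: Bernoulli(`r_sens`) for true
#' ACU cases, Bernoulli(`1 - r_spec`) for non-cases.
#'
#' @param labels 0/1 or logical vector of true ACU status.
#' @param r_sens,r_spec Target sensitivity and specificity.
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return Integer 0/1 vector of flags, same length as `labels`.
#' @export
gen_risk_flags <- function(labels, r_sens, r_spec, seed = NULL) {
  if (r_sens < 0 || r_sens > 1 || r_spec < 0 || r_spec > 1)
    stop_input("r_sens and r_spec must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  labels <- as.logical(labels)
  p <- ifelse(labels, r_sens, 1 - r_spec)
  stats::rbinom(length(labels), 1L, p)
}

#' Generate a complete synthetic study
#'
#' Seeds the RNG once from `cfg$seed`, then generates the fee schedule,
#' cohort with service streams, and risk flags, optionally writing every
#' table in the CSV layouts consumed by [parse_fee_schedule()] and the
#' pipeline (`fee_schedule.csv`, `gpci.csv`, `cf.csv`, `services.csv`,
#' `cohort.csv`, `flags.csv`).  One seed reproduces every emitted file
#' byte-for-byte.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional output directory.
#' @return List with `table` (fee schedule), `cohort`, `services`, `flags`.
#' @export
gen_synthetic_study <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  table <- gen_fee_schedule(cfg)
  cs <- gen_cohort(cfg, table)
  flags <- gen_risk_flags(cs$cohort$acu_flag, cfg$r_sens, cfg$r_spec)
  out <- list(table = table, cohort = cs$cohort, services = cs$services,
              flags = data.frame(patient_id = cs$cohort$patient_id,
                                 flag = flags))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fee_schedule(table, dir)
    sv <- out$services
    sv$service_date <- format(sv$service_date, "%Y-%m-%d")
    utils::write.csv(sv, file.path(dir, "services.csv"), row.names = FALSE)
    co <- out$cohort
    co$therapy_start <- format(co$therapy_start, "%Y-%m-%d")
    utils::write.csv(co, file.path(dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(out$flags, file.path(dir, "flags.csv"), row.names = FALSE)
  }
  out
}
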