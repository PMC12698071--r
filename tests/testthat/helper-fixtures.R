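# In-code fixtures shared across test files.

# Minimal single-year fee schedule with one drug code.
tiny_schedule <- function(year = 2020L) {
  entries <- expand.grid(code = c("P0001", "P0002", "J0001"),
                         year = year, quarter = 1:4,
                         stringsAsFactors = FALSE)
  entries$work_rvu <- c(1.3, 0.5, 0.2)[match(entries$code,
                                             c("P0001", "P0002", "J0001"))]
  entries$pe_rvu <- c(0.7, 0.4, 0.1)[match(entries$code,
                                           c("P0001", "P0002", "J0001"))]
  entries$mp_rvu <- c(0.1, 0.05, 0.02)[match(entries$code,
                                             c("P0001", "P0002", "J0001"))]
  entries$asp_price <- ifelse(entries$code == "J0001",
                              100 + 10 * (entries$quarter - 1), NA_real_)
  fee_schedule(
    entries,
    gpci = data.frame(year = year, work_gpci = 1.0, pe_gpci = 1.1,
                      mp_gpci = 0.9),
    cf = data.frame(year = year, cf = 33.0)
  )
}

# Schedule in which every code costs exactly `fee` dollars in every quarter
# (work RVU = fee/cf, unit GPCI), so expected costs are easy to reason about.
flat_schedule <- function(codes = "S0001", fee = 50, year = 2020L) {
  entries <- expand.grid(code = codes, year = year, quarter = 1:4,
                         stringsAsFactors = FALSE)
  entries$work_rvu <- fee
  entries$pe_rvu <- 0
  entries$mp_rvu <- 0
  entries$asp_price <- NA_real_
  fee_schedule(
    entries,
    gpci = data.frame(year = year, work_gpci = 1, pe_gpci = 1, mp_gpci = 1),
    cf = data.frame(year = year, cf = 1)
  )
}

# Brute-force Mann-Whitney U for sample a: #(a_i > b_j) + ties/2.
pair_count_U <- function(a, b) {
  gt <- sum(outer(a, b, ">"))
  ties <- sum(outer(a, b, "=="))
  gt + ties / 2
}

# Small synthetic study used by several files; cached per session.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 404L, n_patients = 400L, n_codes = 40L)
      cache <<- list(cfg = cfg, study = gen_synthetic_study(cfg))
    }
    cache
  }
})
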