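#' Construct a quarterly Medicare fee schedule
#'
#' Bundles per-code relative value units (RVUs) and average sales prices
#' (ASP) with annual geographic practice cost indices (GPCI) and conversion
#' factors (CF) into a single validated lookup table.  Fees are resolved per
#' HCPCS/CPT code per calendar quarter: professional services are paid under
#' the Medicare Physician Fee Schedule (MPFS) three-component formula and
#' drug codes additionally carry the CMS payment limit of 106% of ASP.
#'
#' @param entries data.frame with columns `code`, `year`, `quarter`,
#'   `work_rvu`, `pe_rvu`, `mp_rvu`, `asp_price`.  `asp_price` may be `NA`
#'   for non-drug codes.  `(code, year, quarter)` must be unique.
#' @param gpci data.frame with columns `year`, `work_gpci`, `pe_gpci`,
#'   `mp_gpci`; one row per year (single locality).
#' @param cf data.frame with columns `year`, `cf` (dollars per weighted RVU).
#' @return An object of class `fee_schedule`.
#' @seealso [parse_fee_schedule()], [combined_fee()]
#' @export
fee_schedule <- function(entries, gpci, cf) {
  entries <- as.data.frame(entries)
  gpci <- as.data.frame(gpci)
  cf <- as.data.frame(cf)

  need <- c("code", "year", "quarter", "work_rvu", "pe_rvu", "mp_rvu", "asp_price")
  if (!all(need %in% names(entries)))
    stop_input("fee entries must have columns: ", paste(need, collapse = ", "))
  if (!all(c("year", "work_gpci", "pe_gpci", "mp_gpci") %in% names(gpci)))
    stop_input("gpci must have columns year, work_gpci, pe_gpci, mp_gpci")
  if (!all(c("year", "cf") %in% names(cf)))
    stop_input("cf must have columns year, cf")

  entries$code <- as.character(entries$code)
  entries$year <- as.integer(entries$year)
  entries$quarter <- as.integer(entries$quarter)
  for (col in c("work_rvu", "pe_rvu", "mp_rvu", "asp_price"))
    entries[[col]] <- as.numeric(entries[[col]])

  bad_q <- !entries$quarter %in% 1:4
  if (any(bad_q))
    stop_input("malformed quarter (must be 1-4) in fee entries: rows ",
               paste(utils::head(which(bad_q), 5), collapse = ", "))
  rvus <- as.matrix(entries[c("work_rvu", "pe_rvu", "mp_rvu")])
  if (anyNA(rvus) || any(rvus < 0))
    stop_input("RVU components must be present and >= 0")
  if (any(entries$asp_price < 0, na.rm = TRUE))
    stop_input("asp_price must be >= 0 when present")

  key <- paste(entries$code, entries$year, entries$quarter, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_input("duplicate fee-schedule key (code|year|quarter): ", dup)
  }

  if (anyDuplicated(gpci$year)) stop_input("duplicate year in GPCI table")
  if (anyDuplicated(cf$year)) stop_input("duplicate year in conversion-factor table")
  if (any(gpci$work_gpci <= 0 | gpci$pe_gpci <= 0 | gpci$mp_gpci <= 0))
    stop_input("all GPCI multipliers must be > 0")
  if (any(cf$cf <= 0)) stop_input("conversion factor must be > 0")

  miss_g <- setdiff(entries$year, gpci$year)
  if (length(miss_g))
    stop_input("fee entries reference year(s) with no GPCI row: ",
               paste(miss_g, collapse = ", "))
  miss_c <- setdiff(entries$year, cf$year)
  if (length(miss_c))
    stop_input("fee entries reference year(s) with no conversion factor: ",
               paste(miss_c, collapse = ", "))

  structure(
    list(entries = entries, gpci = gpci, cf = cf, key = key),
    class = "fee_schedule"
  )
}

#' @export
print.fee_schedule <- function(x, ...) {
  cat("<fee_schedule>\n")
  cat("  codes:   ", length(unique(x$entries$code)), "\n")
  cat("  entries: ", nrow(x$entries), " (code x year x quarter)\n")
  cat("  years:   ", paste(sort(unique(x$entries$year)), collapse = ", "), "\n")
  cat("  drug entries (ASP present): ", sum(!is.na(x$entries$asp_price)), "\n")
  invisible(x)
}

#' Read a fee schedule from its CSV layout
#'
#' Expects three UTF-8 CSV files with header rows:
#' * `fee_file`: `code, year, quarter, work_rvu, pe_rvu, mp_rvu, asp_price`
#'   (empty `asp_price` means the code has no ASP component);
#' * `gpci_file`: `year, work_gpci, pe_gpci, mp_gpci`;
#' * `cf_file`: `year, cf`.
#'
#' Unknown extra columns are dropped with a warning; missing required
#' columns, duplicate `(code, year, quarter)` keys, negative RVUs, malformed
#' quarters, or a year lacking a GPCI/CF row are errors.
#'
#' @param fee_file,gpci_file,cf_file Paths to the three CSV files.
#' @return A validated [fee_schedule()] object.
#' @export
parse_fee_schedule <- function(fee_file, gpci_file, cf_file) {
  for (f in c(fee_file, gpci_file, cf_file))
    if (!file.exists(f)) stop_input("input file not found: ", f)

  read_layout <- function(path, want) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(code = "character")[intersect("code", want)])
    extra <- setdiff(names(df), want)
    if (length(extra)) {
      warning("ignoring unknown column(s) in ", basename(path), ": ",
              paste(extra, collapse = ", "), call. = FALSE)
      df <- df[want[want %in% names(df)]]
    }
    miss <- setdiff(want, names(df))
    if (length(miss))
      stop_input(basename(path), " is missing column(s): ",
                 paste(miss, collapse = ", "))
    df[want]
  }

  fees <- read_layout(fee_file, c("code", "year", "quarter",
                                  "work_rvu", "pe_rvu", "mp_rvu", "asp_price"))
  gpci <- read_layout(gpci_file, c("year", "work_gpci", "pe_gpci", "mp_gpci"))
  cf <- read_layout(cf_file, c("year", "cf"))
  fee_schedule(fees, gpci, cf)
}

#' Write a fee schedule back to its CSV layout
#'
#' Inverse of [parse_fee_schedule()]: emits `fee_schedule.csv`, `gpci.csv`
#' and `cf.csv` under `dir`.  Values are written at full double precision so
#' a write/parse round trip reproduces every fee bit-identically.
#'
#' @param table A [fee_schedule()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_fee_schedule <- function(table, dir) {
  stopifnot(inherits(table, "fee_schedule"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("fee_schedule.csv", "gpci.csv", "cf.csv"))
  write_full <- function(df, path) {
    df2 <- df
    for (col in names(df2))
      if (is.double(df2[[col]]))
        df2[[col]] <- sprintf("%.17g", df2[[col]])
    df2[df == "NA" | is.na(df)] <- ""
    utils::write.csv(df2, path, row.names = FALSE, quote = FALSE, na = "")
  }
  write_full(table$entries, paths[1])
  write_full(table$gpci, paths[2])
  write_full(table$cf, paths[3])
  invisible(paths)
}

#' Calendar quarter of a date
#'
#' @param date A `Date` vector (or anything `as.Date()` accepts).
#' @return data.frame with integer columns `year` and `quarter`
#'   (`quarter = ceiling(month / 3)`).
#' @examples
#' quarter_of(as.Date("2015-07-15"))  # year 2015, quarter 3
#' @export
quarter_of <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (anyNA(d)) stop_input("invalid calendar date")
  lt <- as.POSIXlt(d)
  data.frame(year = lt$year + 1900L,
             quarter = (lt$mon %/% 3L) + 1L)
}

#' Medicare Physician Fee Schedule payment for one entry
#'
#' The standard CMS three-component payment:
#' `(work_rvu * work_gpci + pe_rvu * pe_gpci + mp_rvu * mp_gpci) * cf`.
#'
#' @param entry A single row of fee-schedule entries (list or 1-row
#'   data.frame with the RVU columns and `year`).
#' @param gpci The GPCI row for the same year.
#' @param cf The conversion-factor row for the same year.
#' @return Fee in USD (non-negative scalar).
#' @export
mpfs_fee <- function(entry, gpci, cf) {
  if (!is.null(entry$year) && !is.null(gpci$year) && entry$year != gpci$year)
    stop_input("entry year ", entry$year, " does not match GPCI year ", gpci$year)
  if (!is.null(entry$year) && !is.null(cf$year) && entry$year != cf$year)
    stop_input("entry year ", entry$year, " does not match conversion-factor year ", cf$year)
  (entry$work_rvu * gpci$work_gpci +
     entry$pe_rvu * gpci$pe_gpci +
     entry$mp_rvu * gpci$mp_gpci) * cf$cf
}

#' ASP drug payment: the CMS limit of 106% of average sales price
#'
#' @param asp_price Average sales price in USD per unit (>= 0).
#' @return `1.06 * asp_price`.
#' @export
asp_fee <- function(asp_price) {
  if (any(asp_price < 0, na.rm = TRUE)) stop_input("asp_price must be >= 0")
  ifelse(is.na(asp_price), 0, 1.06 * asp_price)
}

# Vector of combined fees for every entry row of a schedule, in row order.
# MPFS component + 106% ASP (0 where ASP absent).
entry_fees <- function(table) {
  e <- table$entries
  g <- table$gpci[match(e$year, table$gpci$year), ]
  cf <- table$cf$cf[match(e$year, table$cf$year)]
  mpfs <- (e$work_rvu * g$work_gpci + e$pe_rvu * g$pe_gpci +
             e$mp_rvu * g$mp_gpci) * cf
  mpfs + asp_fee(e$asp_price)
}

#' Combined Medicare fee for a code on a date
#'
#' Sum of the MPFS payment and the 106%-of-ASP drug payment for the fee
#' entry in effect in the calendar quarter of `date`.  Entries without an
#' ASP price contribute 0 for the ASP component.  Vectorised over
#' `code`/`date` pairs.
#'
#' @param table A [fee_schedule()] object.
#' @param code HCPCS/CPT code(s).
#' @param date Service date(s).
#' @return Fee(s) in USD.
#' @export
combined_fee <- function(table, code, date) {
  stopifnot(inherits(table, "fee_schedule"))
  code <- as.character(code)
  yq <- quarter_of(date)
  n <- max(length(code), nrow(yq))
  code <- rep_len(code, n)
  key <- paste(code, rep_len(yq$year, n), rep_len(yq$quarter, n), sep = "|")
  idx <- match(key, table$key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    if (!code[bad] %in% table$entries$code)
      stop_input("code never seen in fee schedule: ", code[bad])
    stop_input("code ", code[bad], " has no fee entry for ",
               rep_len(yq$year, n)[bad], " Q", rep_len(yq$quarter, n)[bad])
  }
  entry_fees(table)[idx]
}
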