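# Internal numeric helpers shared across modules.

# Half-up (away from zero) rounding; base round() uses banker's rounding,
# which does not reproduce claims-style arithmetic such as 118.65 -> 119.
# The 1e-9 guard absorbs binary representation error (0.35 etc.).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Floor with a tolerance so that values like 339.9999999 (a decimal product
# that is exact on paper) floor to the intended integer.
floor_tol <- function(x, tol = 1e-9) floor(x + tol)

# Round money to whole cents, half up. Used only at reporting boundaries;
# internal accumulation stays at full double precision.
round_cents <- function(x) round_half_up(x, digits = 2)

# Round to the nearest multiple of `unit` (presentation granularity for
# headline figures, e.g. nearest $10,000).
round_to_unit <- function(x, unit) round_half_up(x / unit) * unit

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
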