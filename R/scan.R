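# Sweeps of a residue-rate profile over one condition variable, including
# the three acidity-control scenarios (fixed pH* read, fixed pL, fixed
# pOL) as presets.

#' Sweep a per-residue profile over one condition variable
#'
#' Evaluates [residue_profile()] across a grid of one scan variable while
#' the remaining condition parameters stay fixed. At most one variable may
#' be scanned per call. The three classic acidity-control scenarios are
#' available as presets scanning the D2O fraction at 25 degC:
#' `"fig1-phread"` (pH* = 7 held), `"fig1-pl"` (pL = 7.43 held) and
#' `"fig1-pol"` (pOL = 7.43 held). With base catalysis, k_int decreases
#' with x at fixed pH*, decreases more steeply at fixed pL, and increases
#' with x at fixed pOL.
#'
#' @param sequence Peptide sequence.
#' @param scan_var One of `"x"`, `"ph_read"`, `"pl"`, `"pol"`,
#'   `"temperature"`.
#' @param grid Numeric grid of scan values.
#' @param x,temperature,ph_read,pl,pol Fixed condition parameters (see
#'   [solvent_condition()]); when an acidity scale is scanned no other
#'   acidity argument may be supplied, and when `x` or `temperature` is
#'   scanned exactly one acidity argument must be.
#' @param preset Optional preset name overriding `scan_var`, `grid` and
#'   the acidity arguments.
#' @param refset A [reference_rates()] set.
#' @param factors A [sequence_factors()] table.
#' @return A long data frame: the scan variable value in `scan_value`
#'   (named by `scan_var` in the attribute of the same name) followed by
#'   the [residue_profile()] columns.
#' @examples
#' sc <- scan_profile("AA", preset = "fig1-phread",
#'                    grid = seq(0, 1, by = 0.5))
#' @export
scan_profile <- function(sequence, scan_var = NULL, grid = NULL,
                         x = NULL, temperature = 298.15,
                         ph_read = NULL, pl = NULL, pol = NULL,
                         preset = NULL,
                         refset = reference_rates("PDLA"),
                         factors = sequence_factors()) {
  if (!is.null(preset)) {
    if (!preset %in% c("fig1-phread", "fig1-pl", "fig1-pol")) {
      abort_config("unknown preset '%s'", preset)
    }
    if (!is.null(ph_read) || !is.null(pl) || !is.null(pol)) {
      abort_config("presets fix the acidity; drop ph_read/pl/pol")
    }
    scan_var <- "x"
    if (is.null(grid)) grid <- seq(0, 1, by = 0.05)
    temperature <- 298.15
    switch(preset,
           "fig1-phread" = ph_read <- 7,
           "fig1-pl" = pl <- 7.43,
           "fig1-pol" = pol <- 7.43)
  }
  if (is.null(scan_var) ||
      !scan_var %in% c("x", "ph_read", "pl", "pol", "temperature")) {
    abort_config("`scan_var` must be one of x, ph_read, pl, pol, temperature")
  }
  if (is.null(grid) || !is.numeric(grid) || length(grid) < 1L) {
    abort_config("`grid` must be a non-empty numeric vector")
  }
  acidity_given <- c(ph_read = !is.null(ph_read), pl = !is.null(pl),
                     pol = !is.null(pol))
  if (scan_var %in% c("ph_read", "pl", "pol")) {
    if (any(acidity_given)) {
      abort_config("cannot scan '%s' while '%s' is fixed", scan_var,
                   names(acidity_given)[acidity_given][1])
    }
    if (is.null(x)) abort_config("fix `x` when scanning an acidity scale")
  } else if (sum(acidity_given) != 1L) {
    abort_config("fix exactly one acidity scale when scanning '%s'", scan_var)
  }
  if (scan_var == "x" && !is.null(x)) {
    abort_config("cannot scan 'x' while `x` is fixed")
  }
  rows <- lapply(grid, function(v) {
    args <- list(x = x, temperature = temperature,
                 ph_read = ph_read, pl = pl, pol = pol)
    args[[scan_var]] <- v
    cond <- do.call(solvent_condition,
                    args[!vapply(args, is.null, logical(1))])
    prof <- residue_profile(sequence, cond, refset, factors)
    cbind(scan_value = v, prof)
  })
  out <- do.call(rbind, rows)
  attr(out, "scan_var") <- scan_var
  out
}
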