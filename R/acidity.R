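# Acidity scales and ion concentrations in H2O/D2O mixtures.
#
# In a mixture the individual isotopologue ionisation equilibria (H2O, HDO,
# D2O and their ions) are not resolved; instead the operational scales
#   pL  = -log10([H+] + [D+])    and    pOL = -log10([OH-] + [OD-])
# are used, tied together by the effective ionic product pKw(x) of the
# mixture, pL + pOL = pKw(x).

#' Ionic product of pure water as a function of temperature
#'
#' Empirical fit for \eqn{pK_{w,H_2O}(T)}, valid over roughly the liquid
#' range of water:
#' \deqn{pK_w = 670.86 - 34691.6/T - 105.15\ln T + 0.10757\,T + 2.358\times 10^6/T^2}
#'
#' @param temperature Absolute temperature in Kelvin (vectorised).
#' @return \eqn{pK_{w,H_2O}} in log10 units (\eqn{-\log_{10} K_w},
#'   \eqn{K_w} in M^2). About 14.00 at 298.15 K.
#' @examples
#' pkw_water(298.15)
#' @export
pkw_water <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    abort_domain("`temperature` must be a positive temperature in Kelvin")
  }
  670.86 - 34691.6 / temperature - 105.15 * log(temperature) +
    0.10757 * temperature + 2358000 / temperature^2
}

#' Ionic-product shift of an H2O/D2O mixture
#'
#' Empirical cubic for the increase of the effective ionic product of the
#' mixture over pure H2O, \eqn{\Delta pK_w(x) = pK_w(x) - pK_{w,H_2O}},
#' as a function of the D2O mole fraction \eqn{x}. The shift is treated as
#' composition-dependent only (evaluated at fixed temperature).
#'
#' @param x D2O mole fraction in \[0, 1\] (vectorised).
#' @return \eqn{\Delta pK_w} in log10 units; 0 at x = 0, 0.8620 at x = 1.
#' @examples
#' delta_pkw(c(0, 0.5, 1))
#' @export
delta_pkw <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_domain("D2O mole fraction `x` must lie in [0, 1]")
  }
  0.7282 * x + 0.0512 * x^2 + 0.0826 * x^3
}

#' Operational acidity pL from a glass-electrode reading
#'
#' Converts an uncorrected glass-electrode pH-meter reading pH* taken in an
#' H2O/D2O mixture into the operational acidity
#' \eqn{pL = -\log_{10}([H^+]+[D^+])} via
#' \deqn{pL(x) = pH^* \left(1 + \Delta pK_w(x) / pK_{w,H_2O}\right)}
#' At x = 1 and 25 degC a reading of 7 gives pL of about 7.43, i.e. the
#' traditional "+0.4" pD correction.
#'
#' @param ph_read Glass-electrode reading pH* (dimensionless log units).
#' @param x D2O mole fraction in \[0, 1\].
#' @param temperature Absolute temperature in Kelvin at which
#'   \eqn{pK_{w,H_2O}} is evaluated. Default 298.15 K.
#' @return pL in log10 units.
#' @examples
#' pl_from_ph_read(7, x = 1)       # ~7.43, the classic pD correction
#' pl_from_ph_read(7, x = 0)       # identical to the reading in pure H2O
#' @export
pl_from_ph_read <- function(ph_read, x, temperature = 298.15) {
  ph_read * (1 + delta_pkw(x) / pkw_water(temperature))
}

#' Specify a solvent condition
#'
#' Bundles the composition, temperature and acidity of an H2O/D2O mixture.
#' Exactly one of the three acidity scales must be fixed: the glass
#' electrode reading `ph_read` (pH*), the operational acidity `pl`, or the
#' operational basicity `pol`.
#'
#' @param x D2O mole fraction in \[0, 1\].
#' @param temperature Absolute temperature in Kelvin. A warning is issued
#'   outside 273--373 K, where the empirical fits are not plausible, and
#'   far from 298 K in a mixture, where the composition-only treatment of
#'   \eqn{\Delta pK_w} is least reliable.
#' @param ph_read,pl,pol The acidity value on exactly one scale.
#' @return An object of class `solvent_condition` with fields `x`,
#'   `temperature`, `acidity_mode` (one of `"ph_read"`, `"pl"`, `"pol"`)
#'   and `acidity_value`.
#' @examples
#' solvent_condition(x = 0.9, ph_read = 7)
#' solvent_condition(x = 1, temperature = 278.15, pl = 7.43)
#' @export
solvent_condition <- function(x, temperature = 298.15,
                              ph_read = NULL, pl = NULL, pol = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort_domain("D2O mole fraction `x` must be a single value in [0, 1]")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    abort_domain("`temperature` must be a single positive value in Kelvin")
  }
  if (temperature < 273 || temperature > 373) {
    warning("temperature ", temperature,
            " K is outside 273-373 K; the empirical pKw fits are ",
            "extrapolated", call. = FALSE)
  } else if (x > 0 && abs(temperature - 298.15) > 15) {
    warning("the mixture ionic-product shift is treated as ",
            "composition-dependent only; accuracy degrades far from 298 K",
            call. = FALSE)
  }
  given <- list(ph_read = ph_read, pl = pl, pol = pol)
  set <- !vapply(given, is.null, logical(1))
  if (sum(set) != 1L) {
    abort_config(
      "exactly one of `ph_read`, `pl`, `pol` must be given (got %d)",
      sum(set))
  }
  mode <- names(given)[set]
  value <- given[[mode]]
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    abort_config("acidity value on scale '%s' must be a single number", mode)
  }
  structure(
    list(x = x, temperature = temperature,
         acidity_mode = mode, acidity_value = value),
    class = "solvent_condition")
}

#' @export
print.solvent_condition <- function(x, ...) {
  cat(sprintf("<solvent_condition> x(D2O) = %.4g, T = %.2f K, %s = %.4g\n",
              x$x, x$temperature, x$acidity_mode, x$acidity_value))
  invisible(x)
}

#' Resolve the ionic state of a solvent condition
#'
#' Computes pL, pOL and the catalytic ion concentrations implied by a
#' [solvent_condition()]. The mixture ionic product is
#' \eqn{pK_w(x) = pK_{w,H_2O}(T) + \Delta pK_w(x)}; whichever acidity scale
#' was fixed is converted to pL (pH* via [pl_from_ph_read()]) and the other
#' scale follows by subtraction. The total lyoxide concentration
#' \eqn{[OL^-] = 10^{-pOL}} is partitioned between the isotopologues in
#' proportion to the solvent composition:
#' \eqn{[OD^-] = x\,[OL^-]}, \eqn{[OH^-] = (1-x)\,[OL^-]}.
#'
#' @param condition A [solvent_condition()].
#' @return An object of class `ion_state` with fields `pL`, `pOL`,
#'   `pKw_mix`, `conc_OL`, `conc_OH`, `conc_OD` (mol/L) plus the `x` and
#'   `temperature` of the condition.
#' @examples
#' ion_state(solvent_condition(x = 1, ph_read = 7))
#' @export
ion_state <- function(condition) {
  if (!inherits(condition, "solvent_condition")) {
    abort_config("`condition` must be created with solvent_condition()")
  }
  pkw_mix <- pkw_water(condition$temperature) + delta_pkw(condition$x)
  pl <- switch(condition$acidity_mode,
    ph_read = pl_from_ph_read(condition$acidity_value, condition$x,
                              condition$temperature),
    pl  = condition$acidity_value,
    pol = pkw_mix - condition$acidity_value,
    abort_config("unknown acidity mode '%s'", condition$acidity_mode))
  pol <- pkw_mix - pl
  conc_od <- condition$x * 10^(-pol)
  conc_oh <- (1 - condition$x) * 10^(-pol)
  structure(
    list(pL = pl, pOL = pol, pKw_mix = pkw_mix,
         conc_OL = conc_oh + conc_od,  # exact conservation by construction
         conc_OH = conc_oh,
         conc_OD = conc_od,
         x = condition$x, temperature = condition$temperature),
    class = "ion_state")
}

#' @export
print.ion_state <- function(x, ...) {
  cat(sprintf(
    "<ion_state> pL = %.4f, pOL = %.4f, pKw(x) = %.4f\n  [OL-] = %.4g M ([OH-] = %.4g, [OD-] = %.4g)\n",
    x$pL, x$pOL, x$pKw_mix, x$conc_OL, x$conc_OH, x$conc_OD))
  invisible(x)
}
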