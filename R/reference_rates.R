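# Isotope-resolved second-order reference rates for base-catalysed amide
# exchange. The two-letter index gives first the amide-bound isotope being
# removed and second the isotope of the abstracting lyoxide:
#   kHH = NH + OH-,  kDH = ND + OH-,  kHD = NH + OD-,  kDD = ND + OD-.
# kDD is not measured and is filled in from the zero-point-energy estimate
# kDD = kHD * kDH / kHH.

# gas constant in cal mol^-1 K^-1 (activation energies are in kcal/mol)
.R_CAL <- 1.98720425864083

#' Reference second-order base-catalysis rates
#'
#' Returns the four isotope-resolved second-order rate constants
#' (log10 scale, M^-1 min^-1) for the random-coil calibration standard:
#' poly-DL-alanine (`"PDLA"`, the default) with
#' log kHH = 10.08, log kDH = 10.00, log kHD = 10.18 at 20 degC, or
#' tri-alanine (`"3Ala"`), whose rates are 1.35 times the PDLA rates on the
#' linear scale. The unmeasured kDD is auto-filled via [kdd_estimate()].
#' A single activation energy of 17 kcal/mol is attached for Arrhenius
#' temperature scaling of all four rates.
#'
#' @param standard `"PDLA"` or `"3Ala"`.
#' @return An object of class `reference_rate_set` with fields `log_kHH`,
#'   `log_kDH`, `log_kHD`, `log_kDD`, `t_ref` (K), `activation_energy`
#'   (kcal/mol) and `standard`.
#' @examples
#' reference_rates()           # PDLA
#' reference_rates("3Ala")
#' @export
reference_rates <- function(standard = c("PDLA", "3Ala")) {
  if (!is.character(standard) || !standard[1] %in% c("PDLA", "3Ala")) {
    abort_config("unknown reference standard '%s' (use \"PDLA\" or \"3Ala\")",
                 as.character(standard[1]))
  }
  standard <- standard[1]
  shift <- if (standard == "3Ala") log10(1.35) else 0
  reference_rate_set(log_kHH = 10.08 + shift,
                     log_kDH = 10.00 + shift,
                     log_kHD = 10.18 + shift,
                     t_ref = 293.15, activation_energy = 17,
                     standard = standard)
}

#' Construct a reference rate set
#'
#' Low-level constructor for custom rate sets (e.g. acid- or
#' water-catalysis extensions). If `log_kDD` is omitted it is auto-filled
#' with [kdd_estimate()], which enforces kHH * kDD = kHD * kDH.
#'
#' @param log_kHH,log_kDH,log_kHD,log_kDD log10 second-order rate
#'   constants (M^-1 min^-1).
#' @param t_ref Reference temperature (K) at which the rates were measured.
#' @param activation_energy Arrhenius activation energy (kcal/mol), shared
#'   by all four rates.
#' @param standard Label for the calibration standard.
#' @return An object of class `reference_rate_set`.
#' @export
reference_rate_set <- function(log_kHH, log_kDH, log_kHD, log_kDD = NULL,
                               t_ref = 293.15, activation_energy = 17,
                               standard = "custom") {
  for (v in list(log_kHH, log_kDH, log_kHD, t_ref, activation_energy)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort_config("reference rate parameters must be single finite numbers")
    }
  }
  if (t_ref <= 0) abort_domain("`t_ref` must be positive (Kelvin)")
  set <- structure(
    list(log_kHH = log_kHH, log_kDH = log_kDH, log_kHD = log_kHD,
         log_kDD = NA_real_, t_ref = t_ref,
         activation_energy = activation_energy, standard = standard),
    class = "reference_rate_set")
  set$log_kDD <- if (is.null(log_kDD)) kdd_estimate(set) else log_kDD
  set
}

#' @export
print.reference_rate_set <- function(x, ...) {
  cat(sprintf(
    "<reference_rate_set> %s @ %.2f K, E_B = %g kcal/mol\n  log10 k (M^-1 min^-1): HH %.4f, DH %.4f, HD %.4f, DD %.4f\n",
    x$standard, x$t_ref, x$activation_energy,
    x$log_kHH, x$log_kDH, x$log_kHD, x$log_kDD))
  invisible(x)
}

#' Estimate the unmeasured ND + OD- rate
#'
#' The D-from-D abstraction rate is not experimentally available; assuming
#' the rates are governed by the zero-point energies of the participating
#' species it is estimated as \eqn{k_{DD} = k_{HD} k_{DH} / k_{HH}}
#' (log form: log kHD + log kDH - log kHH), which makes the ratio identity
#' \eqn{k_{HH} k_{DD} = k_{HD} k_{DH}} exact.
#'
#' @param set A `reference_rate_set` (the `log_kDD` field is ignored).
#' @return log10 kDD (M^-1 min^-1).
#' @examples
#' kdd_estimate(reference_rates())  # 10.10 for PDLA
#' @export
kdd_estimate <- function(set) {
  set$log_kHD + set$log_kDH - set$log_kHH
}

#' Arrhenius temperature scaling of a log rate constant
#'
#' Applies \eqn{k(T) = k(T_{ref}) \exp[-(E/R)(1/T - 1/T_{ref})]} on the
#' log10 scale.
#'
#' @param log_k_ref log10 rate at the reference temperature.
#' @param t_ref Reference temperature (K).
#' @param temperature Target temperature (K).
#' @param activation_energy Activation energy in kcal/mol.
#' @return log10 rate at `temperature`.
#' @examples
#' arrhenius_scale(10.08, 293.15, 298.15, 17)
#' @export
arrhenius_scale <- function(log_k_ref, t_ref, temperature,
                            activation_energy = 17) {
  if (any(!is.finite(t_ref)) || any(t_ref <= 0) ||
      any(!is.finite(temperature)) || any(temperature <= 0)) {
    abort_domain("temperatures must be positive (Kelvin)")
  }
  log_k_ref -
    (activation_energy * 1000 / .R_CAL) * (1 / temperature - 1 / t_ref) /
      log(10)
}

# linear-scale second-order rates of a set, Arrhenius-scaled to `temperature`
scaled_linear_rates <- function(set, temperature) {
  sc <- function(lk) 10^arrhenius_scale(lk, set$t_ref, temperature,
                                        set$activation_energy)
  list(kHH = sc(set$log_kHH), kDH = sc(set$log_kDH),
       kHD = sc(set$log_kHD), kDD = sc(set$log_kDD))
}
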