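# Forward/back exchange engine. The amide reaction in a mixture,
#   NH + DOL <=> ND + HOL,
# is base-catalysed: the bottleneck is abstraction of the amide-bound
# isotope by OH- or OD-, followed by fast relabelling from bulk solvent.
# Second-order reference rates (per abstraction channel) combine with the
# catalyst concentrations into bidirectional rate constants, which are then
# weighted by the probability that reprotonation inserts the other isotope.

#' Second-order-derived bidirectional rate constants
#'
#' Sums the base-catalysed abstraction channels into the rate constants of
#' the mixture exchange reaction (before solvent-insertion weighting):
#' \deqn{\tilde k_{forw} = k_{HH} B_H [OH^-] + k_{HD} B_D [OD^-]}
#' \deqn{\tilde k_{back} = k_{DH} B_H [OH^-] + k_{DD} B_D [OD^-]}
#' where \eqn{B_H} and \eqn{B_D} are the sequence-factor products for
#' abstraction by OH- and OD- respectively, and all second-order rates are
#' Arrhenius-scaled to the temperature of the ion state.
#'
#' @param ions An [ion_state()].
#' @param refset A [reference_rates()] set.
#' @param b_h,b_d Sequence-factor products (B_lambda x B_rho) for the
#'   H-abstraction and D-abstraction channels; 1 for a PDLA-like context.
#' @return A list with `tilde_forward` and `tilde_backward` (min^-1).
#' @export
tilde_rates <- function(ions, refset, b_h = 1, b_d = 1) {
  if (!inherits(ions, "ion_state")) {
    abort_config("`ions` must be created with ion_state()")
  }
  if (ions$conc_OH < 0 || ions$conc_OD < 0) {
    abort_domain("negative catalyst concentration: inconsistent ion state")
  }
  k <- scaled_linear_rates(refset, ions$temperature)
  list(
    tilde_forward  = k$kHH * b_h * ions$conc_OH + k$kHD * b_d * ions$conc_OD,
    tilde_backward = k$kDH * b_h * ions$conc_OH + k$kDD * b_d * ions$conc_OD)
}

#' Solvent-insertion weighting of bidirectional rates
#'
#' After abstraction, the amide is relabelled by a solvent molecule: a
#' deuteron is inserted with probability x (the D2O mole fraction) and a
#' proton with probability 1 - x. The pseudo-first-order rates are
#' therefore \eqn{k_{forw} = x\,\tilde k_{forw}} and
#' \eqn{k_{back} = (1-x)\,\tilde k_{back}}.
#'
#' @param x D2O mole fraction in \[0, 1\].
#' @param tilde_forward,tilde_backward Rates from [tilde_rates()] (min^-1).
#' @return A list with `k_forward` and `k_backward` (min^-1).
#' @export
weighted_rates <- function(x, tilde_forward, tilde_backward) {
  if (any(x < 0) || any(x > 1)) {
    abort_domain("D2O mole fraction `x` must lie in [0, 1]")
  }
  list(k_forward = x * tilde_forward,
       k_backward = (1 - x) * tilde_backward)
}

#' Equilibrium deuterated fraction of an amide
#'
#' Stationary state of the two-state NH <=> ND kinetics:
#' \eqn{D_{eq} = k_{forw} / (k_{forw} + k_{back})}.
#'
#' @param k_forward,k_backward Pseudo-first-order rates (min^-1).
#' @return `d_eq` in \[0, 1\].
#' @export
equilibrium_deuteration <- function(k_forward, k_backward) {
  if (any(k_forward < 0) || any(k_backward < 0)) {
    abort_domain("rates must be non-negative")
  }
  tot <- k_forward + k_backward
  if (any(tot == 0)) {
    abort_domain("equilibrium undefined: both rates are zero")
  }
  k_forward / tot
}

#' Intrinsic exchange rate in the mixture
#'
#' The approach-to-equilibrium rate of the two-state kinetics,
#' \eqn{k_{int}(x) = k_{forw}(x) + k_{back}(x)}. It reduces to the back
#' rate in pure H2O and to the forward rate in pure D2O.
#'
#' @param k_forward,k_backward Pseudo-first-order rates (min^-1).
#' @return `k_int` (min^-1).
#' @export
mixture_rate <- function(k_forward, k_backward) {
  if (any(k_forward < 0) || any(k_backward < 0)) {
    abort_domain("rates must be non-negative")
  }
  k_forward + k_backward
}

#' Deuterium uptake curve
#'
#' Exponential relaxation of the normalised deuterated fraction toward its
#' equilibrium value:
#' \deqn{D(t) = D_{eq} + (D_0 - D_{eq}) e^{-k_{int} t}}
#' which satisfies the two-state rate equation with conserved total amide
#' concentration and the initial condition D(0) = D_0.
#'
#' @param d0 Initial deuterated fraction in \[0, 1\].
#' @param d_eq Equilibrium deuterated fraction in \[0, 1\].
#' @param k_int_mix Intrinsic mixture rate (min^-1), >= 0.
#' @param times Sampling times (min), non-negative.
#' @return A data frame of class `uptake_curve` with columns `time` and `d`.
#' @examples
#' uptake_curve(0, 0.9, 2, times = c(0, 0.1, 1, 10))
#' @export
uptake_curve <- function(d0, d_eq, k_int_mix, times) {
  if (any(times < 0)) abort_domain("`times` must be non-negative")
  if (d0 < 0 || d0 > 1 || d_eq < 0 || d_eq > 1) {
    abort_domain("`d0` and `d_eq` must lie in [0, 1]")
  }
  if (k_int_mix < 0) abort_domain("`k_int_mix` must be non-negative")
  times <- sort(times)
  out <- data.frame(time = times,
                    d = d_eq + (d0 - d_eq) * exp(-k_int_mix * times))
  attr(out, "d0") <- d0
  attr(out, "d_eq") <- d_eq
  attr(out, "k_int_mix") <- k_int_mix
  class(out) <- c("uptake_curve", class(out))
  out
}

#' Observed exchange rate under protection
#'
#' In the fast-dynamics (EX2-like) limit of the Linderstrom-Lang scheme the
#' observed rate is the intrinsic rate attenuated by the protection factor:
#' \eqn{k_{obs} = k_{int} / (1 + P)}.
#'
#' @param k_int_mix Intrinsic rate (min^-1).
#' @param protection_factor P >= 0.
#' @return `k_obs` (min^-1).
#' @export
observed_rate <- function(k_int_mix, protection_factor) {
  if (any(protection_factor < 0)) {
    abort_domain("`protection_factor` must be non-negative")
  }
  k_int_mix / (1 + protection_factor)
}

#' Per-residue exchange-rate profile of a peptide
#'
#' Applies the full pipeline (ion state, Arrhenius-scaled reference rates,
#' sequence factors, insertion weighting) to every backbone amide of a
#' peptide. Residue 1 and prolines carry no exchangeable amide hydrogen and
#' are emitted with NA rates and an explanatory flag rather than dropped,
#' so rows align with sequence positions.
#'
#' @param sequence Peptide sequence (one-letter string).
#' @param condition A [solvent_condition()].
#' @param refset A [reference_rates()] set.
#' @param factors A [sequence_factors()] table.
#' @return A data frame with one row per residue: `index`, `residue`,
#'   `exchanging`, `b_h`, `b_d`, `tilde_forward`, `tilde_backward`,
#'   `k_forward`, `k_backward`, `k_int`, `d_eq`, `flag`. Rates in min^-1.
#' @examples
#' residue_profile("PEPTIDE", solvent_condition(x = 0.9, ph_read = 7))
#' @export
residue_profile <- function(sequence, condition,
                            refset = reference_rates("PDLA"),
                            factors = sequence_factors()) {
  sequence <- peptide(sequence)
  ions <- ion_state(condition)
  letters <- strsplit(sequence, "")[[1]]
  n <- length(letters)
  out <- data.frame(
    index = seq_len(n), residue = letters, exchanging = FALSE,
    b_h = NA_real_, b_d = NA_real_,
    tilde_forward = NA_real_, tilde_backward = NA_real_,
    k_forward = NA_real_, k_backward = NA_real_,
    k_int = NA_real_, d_eq = NA_real_, flag = "",
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (i == 1) {
      out$flag[i] <- "n-terminal"
      next
    }
    if (letters[i] == "P") {
      out$flag[i] <- "proline"
      next
    }
    b_h <- sequence_factor(sequence, i, "H_base", factors)
    b_d <- sequence_factor(sequence, i, "D_base", factors)
    tk <- tilde_rates(ions, refset, b_h, b_d)
    wk <- weighted_rates(condition$x, tk$tilde_forward, tk$tilde_backward)
    out$exchanging[i] <- TRUE
    out$b_h[i] <- b_h
    out$b_d[i] <- b_d
    out$tilde_forward[i] <- tk$tilde_forward
    out$tilde_backward[i] <- tk$tilde_backward
    out$k_forward[i] <- wk$k_forward
    out$k_backward[i] <- wk$k_backward
    out$k_int[i] <- mixture_rate(wk$k_forward, wk$k_backward)
    out$d_eq[i] <- equilibrium_deuteration(wk$k_forward, wk$k_backward)
  }
  attr(out, "condition") <- condition
  attr(out, "standard") <- refset$standard
  attr(out, "table_version") <- attr(factors, "table_version")
  out
}

#' Bidirectional rates with acid- and water-catalysed channels
#'
#' Optional extension of [tilde_rates()] that adds acid-catalysed
#' (\eqn{[L^+]}-driven) and water-catalysed (\eqn{[L_2O]}-driven) terms to
#' both directions, each channel carrying its own isotope-resolved
#' reference set and the same composition partition used for the lyoxide
#' (the acid channel splits \eqn{[L^+]} as \eqn{x[L^+]} deuteron /
#' \eqn{(1-x)[L^+]} proton, the water channel splits the fixed total
#' solvent molarity of 55.5 M the same way). The insertion weighting of
#' [weighted_rates()] applies downstream unchanged. The base channel is the
#' validated path; the acid and water channels are an extrapolation of the
#' same construction and are disabled unless reference sets are supplied.
#'
#' @param ions An [ion_state()].
#' @param refset_base Base-catalysis [reference_rates()] set.
#' @param refset_acid,refset_water Optional `reference_rate_set`s for the
#'   acid- and water-catalysed channels (log10 M^-1 min^-1; the water set
#'   is interpreted against solvent molarity). `NULL` disables a channel.
#' @param b_h,b_d Sequence-factor products, applied to the base channel.
#' @return A list with `tilde_forward` and `tilde_backward` (min^-1).
#' @export
extended_rates <- function(ions, refset_base, refset_acid = NULL,
                           refset_water = NULL, b_h = 1, b_d = 1) {
  out <- tilde_rates(ions, refset_base, b_h, b_d)
  x <- ions$x
  add_channel <- function(set, conc_total) {
    k <- scaled_linear_rates(set, ions$temperature)
    conc_d <- x * conc_total
    conc_h <- (1 - x) * conc_total
    list(forward = k$kHH * conc_h + k$kHD * conc_d,
         backward = k$kDH * conc_h + k$kDD * conc_d)
  }
  if (!is.null(refset_acid)) {
    if (!inherits(refset_acid, "reference_rate_set")) {
      abort_config("`refset_acid` must be a reference_rate_set")
    }
    ch <- add_channel(refset_acid, 10^(-ions$pL))
    out$tilde_forward <- out$tilde_forward + ch$forward
    out$tilde_backward <- out$tilde_backward + ch$backward
  }
  if (!is.null(refset_water)) {
    if (!inherits(refset_water, "reference_rate_set")) {
      abort_config("`refset_water` must be a reference_rate_set")
    }
    ch <- add_channel(refset_water, 55.5)
    out$tilde_forward <- out$tilde_forward + ch$forward
    out$tilde_backward <- out$tilde_backward + ch$backward
  }
  out
}
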