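---
title: "Intrinsic exchange rates in H2O/D2O mixtures: model and design notes"
author: "hdxmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic exchange rates in H2O/D2O mixtures: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxmix)
```

## The model and its assumptions

`hdxmix` models the chemistry of a fully solvent-exposed backbone amide in
an H2O/D2O mixture of D2O mole fraction $x$. Exchange is treated as
base-catalysed only: the rate-limiting step is abstraction of the
amide-bound isotope by a lyoxide ion (OH$^-$ or OD$^-$), followed by fast
relabelling from bulk solvent. Acid- and water-catalysed channels, which
matter several pH units away from neutrality, are available only through
the explicitly experimental `extended_rates()` and are off by default.

Four second-order abstraction channels are distinguished by the isotope
removed and the abstracting base: $k_{HH}, k_{DH}, k_{HD}, k_{DD}$
(log10 values 10.08, 10.00, 10.18, 10.10 M$^{-1}$min$^{-1}$ for the
poly-DL-alanine standard at 20&nbsp;°C). Three are measured; $k_{DD}$ is
estimated from the zero-point-energy argument
$k_{DD} = k_{HD}k_{DH}/k_{HH}$, which also forces the exact identity
$k_{HH}k_{DD} = k_{HD}k_{DH}$ at every temperature because a single
activation energy (17 kcal/mol) Arrhenius-scales all four rates. The
bidirectional rate constants are channel sums weighted by the catalyst
concentrations, and the pseudo-first-order rates add the probability that
reinsertion from solvent deposits the *other* isotope ($x$ for D,
$1-x$ for H):

$$k_{forw}(x) = x\left[k_{HH}B_H[\mathrm{OH^-}] + k_{HD}B_D[\mathrm{OD^-}]\right],
\qquad
k_{back}(x) = (1-x)\left[k_{DH}B_H[\mathrm{OH^-}] + k_{DD}B_D[\mathrm{OD^-}]\right].$$

The two-state kinetics NH $\rightleftharpoons$ ND with conserved total
amide concentration relax exponentially with
$k_{int} = k_{forw} + k_{back}$ toward
$D_{eq} = k_{forw}/k_{int}$:

$$D(t) = D_{eq} + (D_0 - D_{eq})\,e^{-k_{int}t}.$$

(Writing the solution with the opposite sign on the transient term — a
form sometimes seen — would give $D(0) = 2D_{eq}-D_0$; the form above is
the one that satisfies both the rate equation and the initial condition,
and is what `uptake_curve()` implements and what the test suite verifies
by numerical differentiation.)

Key consequences, all covered by tests: the pure-solvent limits recover
the single-channel rate laws ($k_{forw}(1) = k_{HD}B_D[\mathrm{OD^-}]$,
$k_{back}(0) = k_{DH}B_H[\mathrm{OH^-}]$); the ratio
$\tilde k_{forw}/\tilde k_{back}$ collapses to the fractionation factor
$\phi = k_{HH}/k_{DH} = 10^{0.08} \approx 1.20$ independently of $x$,
acidity, temperature and sequence; and equilibrium enrichment follows the
closed form $D_{eq}(x) = x\phi/(x\phi + 1 - x) > x$.

## Acidity in a mixture

Individual isotopologue ionisation equilibria are not resolved. The
package works on the operational scales $pL = -\log_{10}([H^+]+[D^+])$
and $pOL = -\log_{10}([OH^-]+[OD^-])$, tied by the effective ionic
product $pK_w(x) = pK_{w,H_2O}(T) + \Delta pK_w(x)$, with the empirical
fits

$$pK_{w,H_2O}(T) = 670.86 - \tfrac{34691.6}{T} - 105.15\ln T + 0.10757\,T
+ \tfrac{2.358\times 10^6}{T^2},
\qquad
\Delta pK_w(x) = 0.7282x + 0.0512x^2 + 0.0826x^3,$$

and the glass-electrode conversion
$pL = pH^*(1 + \Delta pK_w/pK_{w,H_2O})$, which at $x=1$, 25&nbsp;°C
reproduces the practitioners' "+0.4" pD correction. Two modelling choices
here were genuinely open:

* **Evaluating $pK_{w,H_2O}$ at the working temperature** inside the
  electrode conversion, rather than fixing the 25&nbsp;°C value of 14,
  keeps the whole acidity layer temperature-consistent; at 25&nbsp;°C the
  two choices differ by under 0.002 log units.
* **Partitioning the lyoxide pool.** The isotopologue split of
  $[\mathrm{OL^-}]$ is taken linear in composition,
  $[\mathrm{OD^-}] = x[\mathrm{OL^-}]$, $[\mathrm{OH^-}] = (1-x)[\mathrm{OL^-}]$.
  It is the simplest rule consistent with the pure-solvent endpoints and
  with a composition-independent $\phi$; a lyoxide-specific fractionation
  factor would bow the split at intermediate $x$. The rule lives in one
  function (`ion_state()`), is recorded in CLI logs, and is the single
  place to change if a better description becomes available.

$\Delta pK_w(x)$ is treated as composition-dependent only; because the fit
is anchored near room temperature, `solvent_condition()` warns when a
mixture condition departs more than 15 K from 298 K (and always outside
273–373 K, the plausible range of the pure-water fit).

## Tunable parameters

| parameter | units | default | note |
|---|---|---|---|
| `x` | mole fraction | — | D2O content, [0, 1] |
| `temperature` | K | 298.15 | CLI takes °C and converts |
| `ph_read` / `pl` / `pol` | log10 M | exactly one | the scale held fixed defines the scenario |
| `standard` | — | PDLA | `3Ala` multiplies all four rates by 1.35 |
| `activation_energy` | kcal/mol | 17 | shared by all four channels |
| `protection_factor` | — | 0 | attenuates $k_{int}$ as $k_{int}/(1+P)$ |

Rates are natively M$^{-1}$min$^{-1}$ (second order) and min$^{-1}$
(pseudo-first order); serialisation can convert to s$^{-1}$ or h$^{-1}$.

Which acidity scale is held fixed while $x$ varies changes both magnitude
and direction of the kinetic isotope effect — there is no scale-free
answer. At fixed pH\* = 7 the solution stays neutral while $pK_w(x)$
grows, so $[\mathrm{OL^-}]$ falls and $k_{int}$ decreases with $x$
(endpoint ratio $\approx$ 1.8, i.e. roughly 2-fold); at fixed pL the drop
is steeper ($\approx$ 5-fold); at fixed pOL the catalyst pool is constant
and $k_{int}$ *increases* with $x$ by exactly
$k_{HD}/k_{DH} = 10^{0.18} \approx 1.5$. These three sweeps are the
`fig1-phread`, `fig1-pl`, `fig1-pol` presets of `scan_profile()`.

## Sequence factors

Side-chain steric/inductive effects enter as additive log factors: the
amide of residue $i$ uses the $\lambda$ (left-neighbour) factor of residue
$i-1$ and the $\rho$ (own) factor of residue $i$, plus terminal terms for
the amide of residue 2 (free $\alpha$-amine) and of the C-terminal
residue (carboxylate). The shipped table
(`inst/extdata/base_factors_bai1993.tsv`) transcribes the base-catalysis
columns of Bai, Milne, Mayne & Englander (1993) *Proteins* 17, 75–86,
Table 2, with alanine defining the zero of the scale; titratable side
chains are stored in their near-neutral forms (Asp/Glu carboxylate,
neutral His, reduced Cys) and no pL-dependent interpolation is applied —
users working far from neutrality can supply a modified table via
`sequence_factors(path)`. The published factors do not resolve the
abstracting isotope, so the same values serve the OH$^-$ and OD$^-$
channels (`H_base`/`D_base` keys); any refinement would cancel in $\phi$
anyway, which is why $\phi$ is sequence-independent. Residue 1 has no
reported backbone amide hydrogen and prolines none at all; both are
emitted as flagged rows with NA rates so output rows always align with
sequence positions.

## Numerical choices and degenerate inputs

* All rate algebra is done in log10 where possible; linear conversion
  happens once per evaluation. Conservation
  $[\mathrm{OH^-}]+[\mathrm{OD^-}]=[\mathrm{OL^-}]$ is exact by
  construction.
* $D_{eq}$ is undefined when both rates vanish (only possible at $x=0$
  with forward weighting, $x=1$ with back weighting, or zero catalyst);
  this raises a domain error rather than returning NaN. The enrichment
  curve pins its endpoints to (0,0) and (1,1) analytically.
* Errors are classed (`hdxmix_input_error`, `hdxmix_config_error`,
  `hdxmix_domain_error`, plus `hdxmix_no_amide_error`) and the CLI maps
  them to exit codes 2/3/4.
* `make_fixtures()` draws with an isolated RNG stream (caller state
  restored), so fixture generation is bit-reproducible per seed and never
  perturbs user simulations.

## What the generated fixtures do and do not emulate

The fixture generator produces random sequences over a configurable
alphabet, always prepending the two canonical examples (`AAAAAAA`,
`PEPTIDE`). They exercise the sequence-factor bookkeeping — neighbour
effects, terminal corrections, proline gaps — under the model's own
chemistry. They do not emulate structure, so passing property tests says
nothing about protection, EX1 behaviour, buffer/salt/cosolvent effects on
exchange, or side-chain titration away from neutrality; those are outside
the model.

## Problem sizes

The test suite runs the invariant grids at 10 × 5 × 5 condition points,
property loops at a few dozen random conditions, and peptides up to ~20
residues; the whole suite and the acceptance computation are desk-scale
(seconds on one CPU). These sizes were chosen because every quantity in
the model is a closed-form function of condition — nothing is estimated by
simulation — so denser grids only re-sample smooth curves.

## Known limitations

* Acid- and water-catalysed exchange are modelled only through the
  optional, clearly-labelled extrapolation in `extended_rates()`; results
  below pH ~5 should not be trusted to the base-only path.
* Activity coefficients, buffer ionisation and electrode calibration
  beyond the single conversion formula are not modelled.
* The fractionation factor 1.20 applies to unstructured amides;
  structured amides usually show $\phi \lesssim 1$ and are out of scope.
  The measured comparison values (PDLA 1.22, PDLK 1.46) ship as reporting
  constants only, via `phi_reference_values()`.
* $\Delta pK_w(x)$ carries no temperature dependence; far from room
  temperature the acidity layer is an extrapolation (warned).
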