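# shared helpers: independent closed-form oracles and a one-call k_int

# closed-form equilibrium deuteration for base-only catalysis
deq_closed_form <- function(x, phi) x * phi / (x * phi + 1 - x)

# intrinsic mixture rate of a PDLA-like amide (unit sequence factors)
kint_at <- function(cond, refset = reference_rates("PDLA")) {
  tk <- tilde_rates(ion_state(cond), refset)
  wk <- weighted_rates(cond$x, tk$tilde_forward, tk$tilde_backward)
  mixture_rate(wk$k_forward, wk$k_backward)
}

# condition constructor that silences the far-from-298K advisory warning
quiet_condition <- function(...) suppressWarnings(solvent_condition(...))
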