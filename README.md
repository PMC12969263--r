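# hdxmix

Intrinsic (chemical) amide hydrogen–deuterium exchange rates of
unstructured peptides in H₂O/D₂O mixtures.

## The problem

Hydrogen–deuterium exchange (HDX) experiments — HDX-MS labeling buffers at
80–95% D₂O, quench steps at intermediate deuteration, CLEANEX/SOLEXSY-style
NMR — take place in *mixed* solvents, where exchange is intrinsically
bidirectional: every backbone amide simultaneously picks up deuterium
(forward exchange) and loses it again (back exchange). A single
pure-solvent intrinsic rate then describes neither the relaxation rate nor
the equilibrium labeling. `hdxmix` computes, per residue, the forward and
back pseudo-first-order rates, the total intrinsic rate, the equilibrium
deuterated fraction, and the amide fractionation factor, as functions of
the solvent D₂O mole fraction *x*, acidity and temperature — the
quantities needed for physically grounded back-exchange corrections and
for unbiased protection factors from k<sub>obs</sub> = k<sub>int</sub>/(1+P).

## The model

Base-catalysed exchange (dominant near neutrality) is resolved into four
abstraction channels with second-order reference rates k<sub>HH</sub>,
k<sub>DH</sub>, k<sub>HD</sub>, k<sub>DD</sub> (first index: amide-bound
isotope removed; second: isotope of the abstracting lyoxide). With
sequence factors B<sub>H</sub>, B<sub>D</sub> (products of published
left/right side-chain factors) and the mixture's catalyst concentrations,

```
k̃_forw(x) = k_HH·B_H·[OH⁻](x) + k_HD·B_D·[OD⁻](x)
k̃_back(x) = k_DH·B_H·[OH⁻](x) + k_DD·B_D·[OD⁻](x)
k_forw = x·k̃_forw ,   k_back = (1−x)·k̃_back
k_int(x) = k_forw + k_back ,   D_eq(x) = k_forw / k_int
D(t) = D_eq + (D₀ − D_eq)·e^(−k_int·t)
```

Catalyst concentrations come from the operational acidity scales of the
mixture — the glass-electrode reading pH\*, pL = −log[L⁺] and
pOL = −log[OL⁻] — tied together by the effective ionic product
pK<sub>w</sub>(x) = pK<sub>w,H₂O</sub>(T) + ΔpK<sub>w</sub>(x), with
pL = pH\*·(1 + ΔpK<sub>w</sub>/pK<sub>w,H₂O</sub>) and
[OD⁻] = x·[OL⁻], [OH⁻] = (1−x)·[OL⁻]. The unmeasured k<sub>DD</sub> is
estimated from zero-point energies as k<sub>HD</sub>k<sub>DH</sub>/k<sub>HH</sub>,
and a shared activation energy of 17 kcal/mol scales all four rates with
temperature. A corollary is an x-, pH- and sequence-independent amide
fractionation factor φ = k<sub>HH</sub>/k<sub>DH</sub> ≈ 1.20, so amides
are deuterium-enriched at equilibrium: D<sub>eq</sub>(x) > x.

## Worked example

```r
library(hdxmix)

base_catalyzed_phi(reference_rates("PDLA"))
#> [1] 1.202264                      # amide fractionation factor, ~1.20

pl_from_ph_read(7, x = 1)
#> [1] 7.431011                      # the classic "+0.4" pD correction

cond <- solvent_condition(x = 0.9, ph_read = 7)   # 90% D2O, 25 degC
prof <- residue_profile("PEPTIDE", cond)
prof[, c("index", "residue", "k_forward", "k_backward", "k_int", "d_eq", "flag")]
#>   index residue    k_forward   k_backward        k_int      d_eq       flag
#> 1     1       P           NA           NA           NA        NA n-terminal
#> 2     2       E 16965.990230 1567.9662238 18533.956454 0.9154004
#> 3     3       P           NA           NA           NA        NA    proline
#> 4     4       T   446.251011   41.2417137   487.492724 0.9154004
#> 5     5       I   268.892824   24.8505899   293.743414 0.9154004
#> 6     6       D   675.428237   62.4218597   737.850096 0.9154004
#> 7     7       E     7.405923    0.6844421     8.090365 0.9154004
```

Rates are in min⁻¹; residue 1 and prolines carry no exchangeable amide
hydrogen and are flagged rather than dropped. At x = 0.9 each amide
equilibrates at D<sub>eq</sub> ≈ 0.915 — above the solvent deuterium
fraction because φ > 1 — and the glutamate at position 2 exchanges fastest
(the free α-amine strongly accelerates base catalysis of the second
residue).

A command-line wrapper with `rates`, `scan`, `uptake`, `phi` and
`fixtures` subcommands is installed at
`system.file("cli", "hdxmix.R", package = "hdxmix")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hdxmix.R",package="hdxmix"))')" \
    rates --sequence PEPTIDE --x 0.9 --ph-read 7
```

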