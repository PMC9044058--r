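# itcbind

Equilibrium binding substates from calorimetric titrations, and modal
transport kinetics from single-transporter uptake traces.

## What this package is for

Isothermal titration calorimetry (ITC) of aspartate binding to the
outward-facing state of a sodium-coupled aspartate transporter can show
*bimodal* isotherms: evidence of two conformational substates that
exchange slowly on the experimental timescale, each binding with its own
affinity and enthalpy. This package provides the quantitative machinery
for that analysis, for anyone fitting one- or two-state binding models to
integrated injection heats:

* equilibrium layer: binding polynomial
  `Sigma = 1 + K1[S] + K2[S] + K1K2[S]^2`, fraction bound
  `[PS]/[P] = sum_i n_i K_i [S]/(1 + K_i [S])`, free-ligand mass balance,
  and a three-species competitive extension for displacement titrations;
* perfusion-cell forward model for per-injection heats with dilution-heat
  handling;
* multistart least-squares fitting (`itc_fit()`), AICc/F-test model
  comparison, profile-style identifiability scans, and substate
  population extraction (`100 n2/(n1+n2)`);
* a thermodynamic-cycle free-energy ledger: apo conformational edge
  `RT ln(n1/n2)`, binding edges `RT ln(Kd)`, bound conformational edge by
  cycle closure;
* global shared-rate triexponential fitting of normalized
  single-transporter uptake curves,
  `Y(t) = sum_i f_i (1 - exp(-k_i t))`, with fast/intermediate/slow
  populations per condition (`uptake_fit()`);
* seeded synthetic-data generators for both data types, so the whole
  chain is testable end to end.

## Worked example

Simulate a noisy bimodal titration from the published 500 mM NaCl fitted
parameters (Kd 1.3 / 60.8 nM; dH -3.3 / -7.1 kcal/mol; n 0.64 / 0.22;
40 uM protein, 300 ul cell, 25 x 2 ul injections), refit it, and build
the free-energy ledger:

```r
library(itcbind)
m <- reference_binding_models()$nacl_500mM
iso <- generate_isotherm(m, titration_protocol(), noise_spec(seed = 1))
fit <- itc_fit(iso, model = "two", seed = 1)
fit
#> ITC two-state fit (25 injections, RSS = 0.005811, AICc = -184.17)
#>  parameter  estimate std_error
#>     kd1_nM  1.297819  0.215424
#>     kd2_nM 60.126863  7.734506
#>        dh1 -3.300592  0.012273
#>        dh2 -7.081714  0.093842
#>         n1  0.639262  0.002683
#>         n2  0.220750  0.003336
#>         dq  0.002553  0.004927
#> multistart: 20/20 converged, 4 near the optimum
substate_fraction(fit)
#> [1] 25.66827
build_ledger(fit)
#> Free-energy ledger at 288.15 K (kcal/mol)
#>   apo:    state1 --[+0.61, measured]--> state2
#>   bind:   state1 -11.72   state2 -9.52 (both measured)
#>   bound:  state1 --[+2.80, inferred]--> state2
#>   cycle closure residual: 0
```

The fit recovers the generating parameters within noise (the
high-affinity Kd is the least certain — its Wiseman `c` is ~2e4, and
`scan_identifiability()` shows its profile is locally flat); about 26% of
sites are in the lower-affinity substate, and the ledger says the two
conformations are nearly isoenergetic before binding (+0.6 kcal/mol) but
separated by ~2.8 kcal/mol once substrate is bound, favouring the
high-affinity conformation.

Uptake side, with the published slow-transporter fractions as generating
truths:

```r
ref <- reference_uptake_conditions()
curves <- generate_uptake_curves(ref$fractions, ref$rates,
                                 noise = noise_spec(seed = 5))
uptake_fit(curves, seed = 11)
#> global 3-phase uptake fit (shared rates, 3 conditions)
#> rates (1/s):
#>         fast intermediate         slow
#>     2.731000     0.013870     0.001004
#> phase percentages:
#>           fast intermediate slow
#> NaNO3      3.1          9.3 87.6
#> gluconate  4.4         14.3 81.3
#> NaCl       5.8         14.4 79.8
#> RSS = 0.7235 (fractional scale)
```

The slow fractions (87.6 / 81.3 / 79.8%) land within the published
uncertainties of the generating values (87.3 / 81.1 / 79.5%); the slow
and intermediate rates are recovered while the fast rate is the least
determined parameter (its phase is nearly complete within the first few
samples) — see the vignette.

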