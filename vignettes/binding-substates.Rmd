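---
title: "Modelling two slowly exchanging binding substates from ITC and single-transporter uptake data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two slowly exchanging binding substates from ITC and single-transporter uptake data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcbind)
```

## The scientific problem

Sodium-coupled aspartate transporters of the glutamate-transporter family
can populate long-lived conformational substates of their outward-facing
state. When two such substates exchange slowly on the timescale of an
isothermal titration calorimetry (ITC) experiment, an aspartate titration
no longer follows a simple 1:1 isotherm: it becomes *bimodal*, and is
described by two independent, nonidentical binding states. Each substate
`i` contributes a dissociation constant `Kd_i`, a molar enthalpy `dH_i`,
and an apparent stoichiometry `n_i`; because both substates are the same
site in different conformations, the `n_i` are interpreted as population
fractions (their sum should be near one site per protomer).

This package implements the full quantitative chain for that analysis:

1. the equilibrium layer — binding polynomial, fraction bound, free-ligand
   mass balance, and a three-species competitive extension for
   displacement titrations against a tight blocker;
2. a perfusion-cell ITC forward model mapping a binding model plus
   titration protocol to per-injection heats;
3. multistart nonlinear fitting of single- and two-state models with
   model comparison and identifiability profiling;
4. a free-energy ledger converting fitted populations and affinities into
   the four edges of the conformational/binding thermodynamic cycle;
5. a global shared-rate triexponential analysis of single-transporter
   uptake time courses with fast/intermediate/slow kinetic populations;
6. seeded synthetic-data generators so every stage is testable without any
   instrument files.

## The binding model

For two independent, nonidentical states with association constants
`K_i = 1/Kd_i`, the binding polynomial is

    Sigma = 1 + K1[S] + K2[S] + K1 K2 [S]^2,

and the expected number of occupied sites per protomer is

    [PS]/[P] = n1 K1[S]/(1 + K1[S]) + n2 K2[S]/(1 + K2[S]).

Free ligand [S] is obtained from the total-concentration mass balance by
bracketed bisection on `[0, S_total]` (the residual is strictly monotone,
so the root is unique; a fixed iteration count takes the bracket to a
relative width of 1e-12, which is robust at quantitative-binding
conditions where Newton steps can misbehave). The competitive solver nests
two such bisections (outer over free inhibitor, inner over free
substrate), with per-state occupancies
`theta_S,i = K_i[S] / (1 + K_i[S] + Kinh_i[I])`.

Parameters are stored as dissociation constants in molar units because
the experimental literature reports nanomolar `Kd`s; states are kept in
canonical order of ascending `Kd` (state 1 = higher affinity) to remove
label-swap ambiguity from fits and tests.

## The ITC forward model

The reaction cell is treated as a constant-volume perfusion cell: each
injection of volume `dv` displaces an equal volume of cell content, so
pre-existing species are diluted by `(1 - dv/V0)` while the syringe
contributes `dv/V0` of its concentration. The heat content of the cell
after injection `i` is `Q_i = V0 P_i sum_j n_j dH_j theta_j`, and the
measured heat is

    q_i = Q_i - Q_{i-1} + (dv_i/V0) (Q_i + Q_{i-1})/2 + q_dil m_i,

where the middle term compensates heat carried out with displaced liquid
and `q_dil` is a constant dilution heat per mole of injectant `m_i`. A
constant `q_dil` matches the standard correction practice of subtracting
the mean post-saturation injection heat, which `correct_dilution_heats()`
implements. Two consequences worth knowing:

* the integrated heat equals `V0 P0 sum_j n_j dH_j` only when saturation
  is reached promptly (protein displaced from the cell before it is
  saturated takes its unrealized binding heat with it) — the conservation
  tests therefore use a concentrated syringe;
* some instrument-software conventions model an overfilled rather than a
  perfusion cell; that alternative is documented but not implemented, and
  fitted parameters here are defined with respect to the perfusion
  convention.

Default protocol: a 300 ul cell, 40 uM protein, 25 x 2 ul injections, and
a 600 uM syringe (about 2.5 molar equivalents over the titration) —
typical values for a small-volume instrument and the protein
concentrations used in the experiments this package models.

```{r forward}
m <- reference_binding_models()$nacl_500mM
m
iso <- simulate_injection_heats(m, titration_protocol())
head(as.data.frame(iso), 3)
```

## Fitting and identifiability

`itc_fit()` minimizes unweighted squared residuals of the normalized
heats (per-point uncertainties are not available from integrated heats,
and unweighted fitting matches common instrument software). Optimization
runs in a transformed space — `log10(Kd)` because affinities span
decades, linear enthalpies, stoichiometries bounded to `(0, 3]`, plus a
free dilution offset — with Levenberg–Marquardt from 20 starting points
seeded uniformly in `log10(Kd)` over `[1e-10, 1e-5]` M. Multistart is not
optional decoration here: the two-state model is famously degenerate, and
the dispersion of the starts is reported with every fit. The first
injection can be excluded (`exclude_first`), but is kept by default.

Model choice between single- and two-state fits uses AICc with a
secondary F-test for the nested pair; the more complex model must improve
AICc by a configurable margin (default 2).

Identifiability deserves its own tool because the Wiseman parameter
`c = n [P]/Kd` reaches ~2e4 for the high-affinity substate under these
conditions: the isotherm then constrains that `Kd` only weakly.
`scan_identifiability()` re-optimizes all remaining parameters on a grid
of pinned values (with warm starts carried from the unconstrained optimum
and from neighbouring grid points, as in profile likelihood), and flags a
profile as flat when the re-optimized RSS varies by less than 5% across
the grid. Two practical notes, both established by simulation during
development:

* flatness is a *local* statement — profiles are best taken on grids
  relative to the fitted optimum (e.g. +-10%), where the high-affinity
  `Kd1` of the bimodal condition is flat while the well-determined `Kd2`
  is not, and `Kd1` carries the larger relative standard error;
* over wide grids even `Kd1` shows severalfold RSS changes at the default
  noise level, i.e. it is weakly — not un- — identifiable; its recovered
  values remain usable in the median even though single-experiment values
  scatter far more than `Kd2`'s.

```{r fit}
isoN <- generate_isotherm(m, titration_protocol(), noise_spec(seed = 1))
fit <- itc_fit(isoN, model = "two", seed = 1)
fit
substate_fraction(fit)
```

## The free-energy ledger

Treating the two substates as non-exchanging over the titration, the
fitted populations give the apo conformational free energy
`dG = RT ln(n1/n2)` (a larger state-1 population places state 2 higher,
positive `dG`), the `Kd`s give the binding edges `RT ln(Kd)` at the 1 M
reference, and the substrate-bound conformational edge follows by cycle
closure `dG_conf_apo + dG_bind2 - dG_bind1 - dG_conf_bound = 0`, which
holds to floating-point precision by construction and is labelled
"inferred" in the output. Because `Kd1 < Kd2` and `n1 > n2` in all fitted
salt conditions, the bound-state edge always exceeds the apo edge: the
high-affinity conformation predominates once substrate is bound.

```{r ledger}
build_ledger(fit)
```

## Modal transport kinetics

The single-transporter assay reports cumulative substrate uptake by one
transporter as a FRET-efficiency increase of an encapsulated aspartate
sensor. `normalize_uptake()` follows the published processing rule:
responding traces are averaged per condition, mapped onto a 0–100% scale
using the sensor's 0.2 FRET-efficiency saturation span, multiplied by the
responding fraction, and re-zeroed at the supplied buffer-replacement
time. `uptake_fit()` then fits

    Y(t) = sum_i f_i (1 - exp(-k_i t)),   sum_i f_i = 1,  Y(0) = 0,

with three phases (fast/intermediate/slow), rates shared across
conditions and phase percentages per condition. The percentages are
parameterized through a softmax transform, which enforces the `[0, 100]`
bounds and the sum-to-100 constraint exactly rather than by penalty; the
fitted table is renormalized so rows sum to exactly 100. Averaged curves
are fitted (mean-then-fit), matching how the data are produced; per-trace
fitting is out of scope.

The published slow-transporter fractions (87.3% in nitrate, 81.1% in
gluconate, 79.5% in chloride) serve as generating truths. The rate triple
is not printed in the source experiments; the generator's default
(0.1, 0.01, 0.001 1/s) spans the described orders-of-magnitude
separation. The default time grid is 0–3000 s at 5 s spacing: the slow
phase needs the 3000 s span (three half-lives), while the fast phase
(half-time 7 s) demands the 5 s sampling — on a 10 s grid the
triexponential becomes ill-posed and a spurious near-zero third rate can
beat the generating solution, so the sampling interval is a genuine
design constraint of the emulated experiment, not a free knob. Even so
the fast rate remains the least certain parameter, while the slow
fractions are robust.

```{r uptake}
ref <- reference_uptake_conditions()
curves <- generate_uptake_curves(ref$fractions, ref$rates,
                                 noise = noise_spec(seed = 5))
uptake_fit(curves, seed = 2)
```

## What the synthetic data do and do not emulate

The generators add i.i.d. Gaussian noise: on normalized heats with a
standard deviation of 0.5% of the first injection's heat, and on the
fractional uptake scale with sd 0.02 — magnitudes chosen once to match
the residual scatter visible in published panels, and overridable through
`noise_spec()`. Real data differ in ways the tests therefore cannot
probe: ITC baselines drift and integration errors are correlated between
neighbouring injections; titrant and protein concentrations carry
systematic (not random) errors that bias `n`; uptake traces share
video-level noise and photophysical artefacts. Passing recovery tests
demonstrates that the estimators are consistent and well-conditioned
under the stated noise model, not that every real isotherm yields unique
parameters — indeed the identifiability machinery exists precisely
because some do not.

Replicate counts in the test suite (20 seeded replicates per recovery
condition, 50 for the uptake bias property) were chosen as the smallest
ensembles whose medians are stable to well within the assertion
tolerances.

## Numerical choices and limitations

* Bisection tolerance 1e-12 (relative) for all mass balances; competitive
  solves nest two bisections rather than using a 2-D Newton, trading
  speed for robustness on near-degenerate systems.
* Standard errors come from the Jacobian at the optimum
  (`solve(J'J) * RSS/dof`); they are approximate and, for weakly
  identifiable parameters, optimistic — use the scan for honest
  intervals.
* Fits collapsing to `n -> 0` or to indistinguishable substates (Kds
  within 2-fold *and* enthalpies within 5%) are flagged as effectively
  single-state rather than silently reported.
* Cooperative and sequential binding schemes are deliberately absent
  (they do not describe these data); at most two states are supported.
* Whether published competition isotherms were analysed with a true
  three-species model or phenomenologically is unknown; the competitive
  solver provides the forward machinery without claiming either.
* Enthalpy/entropy decomposition of the conformational step and van't
  Hoff analysis across temperatures are out of scope.
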