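---
title: "Dynamic modeling of signaling-network regions with promoter-driven transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic modeling of signaling-network regions with promoter-driven transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimdyn)
```

## The modeling framework

mimdyn simulates molecular-interaction-map (MIM) style signaling networks
as deterministic ODE systems. A model consists of species — unbound basic
proteins, post-translationally modified forms, multi-protein complexes,
inhibitor molecules and mRNAs — and two reaction classes:

* **Reversible reactions** (binding/unbinding, 1–2 reactants and products)
  with mass-action kinetics `v = kon·∏[reactants] − koff·∏[products]`.
  Units are nM and seconds throughout: `kon` is 1/s (unimolecular) or
  1/(nM·s) (bimolecular), and likewise for `koff` on the product side.
* **Catalytic reactions** (an enzyme converts a substrate into a product of
  identical molecular composition). The default law is the mass-action
  enzyme–substrate product `v = kcat·[E]·[S]` with `kcat` in 1/(nM·s);
  Michaelis–Menten `v = kcat·[E]·[S]/(Km+[S])` is available per reaction
  (`kcat` in 1/s, `Km` in nM). The default is the simpler law, chosen
  because it requires one parameter per reaction and behaves identically
  in the far-from-saturation regime the model mostly occupies; the per-
  reaction flag covers saturable steps.

Every non-mRNA species declares its *composition*, the multiset of basic
proteins it contains. Compositions drive two structural guarantees that
are checked at model validation: **moiety balance** (no reaction creates or
destroys a basic protein; catalysis only converts forms) and **moiety
conservation** (in a closed model, each basic protein's total across all
forms and complexes is constant along any trajectory — the test suite
verifies drift below 1e-6 relative). Reactions with more than two
reactants are rejected; higher-order assembly must be staged through
intermediate complexes, as the destruction-complex example below does.

The simulation protocol mirrors the corresponding wet protocol:

1. each basic protein's total pool is assigned entirely to its unbound
   species (mutation directives are applied at this stage);
2. the system is integrated to **quasi-stationary equilibrium**, which
   redistributes each pool among its forms and complexes — this is the
   pre-treatment baseline;
3. inhibitors are applied as model transformations and the treated system
   is simulated forward; readouts are extracted at the plan's times and
   divided by the vehicle control at the same times.

## The transcription model

MYC and CCND1 share one model promoter with five transcription-factor
binding sites (TCF7L2, SMAD4, AP1, TP53, E2F-DP1). Site occupancy follows
the standard statistical-thermodynamic framework with single occupancy per
site and independence between sites:

$$F_{site} = \frac{1 + \sum_{a}\omega_a [a]/K_{d,a}}
                   {1 + \sum_{a}[a]/K_{d,a} + \sum_{r}[r]/K_{d,r}},
\qquad
F_{reg} = \prod_{site} F_{site},$$

where activators carry an activation weight ω ≥ 1 (the fold increase of
the RNAP-binding weight when the activator is bound) and a bound repressor
excludes RNAP. The RNAP-binding probability is
`P = 1/(1 + ([RNAP]·k_RNAP·F_reg)^-1)` and the mRNA balance is
`d[mRNA]/dt = ksynth·P − kdeg·[mRNA]`. The test suite confirms that the
product-of-sites form agrees exactly with brute-force enumeration of joint
occupancy states on a two-site promoter, which is what the independence
assumption asserts.

The per-site functional form above is a documented default: it is the
competitive-binding occupancy form implied by the framework, with the
exact site-level derivations treated as pluggable (a different `F_site`
can be substituted by replacing `site_regulation_factor()`). Two further
conventions are configurable because the framework admits both readings:
`k_RNAP` is treated as a multiplicative association-type constant (1/nM)
by default, with an inverse-dissociation-constant reading available via
`k_rnap_mode = "inverse_kd"`; and the SMAD4:TCF7L2 activator complex is
assigned to the SMAD4 site (it sits between the two sites conceptually;
the wiring is overridable per run). The AP1 site carries no repressor.

Fixed kinetic constants: `ksynth = 5e-5`/s for both genes (the two genes
are assumed to have equivalent promoters and equal transcription rates),
`kdeg = 2.7e-4`/s for MYC and `5.7e-6`/s for CCND1 — half-lives of 0.71 h
and 33.8 h (`mrna_half_life()`), a ~47-fold stability asymmetry. The fast
MYC pool tracks transcription within a couple of hours; the slow CCND1
pool would barely move on an 8-h experiment, *unless* its stability itself
is regulated, which is the next ingredient.

### MEK-inhibition-dependent CCND1 destabilization

Under a MEK inhibitor the CCND1 degradation rate is rescaled by the ratio
of control to treated ERK phosphorylation:

$$k_{deg,CCND1}^{treated} = k_{deg,CCND1} \cdot
  \frac{[ERKPP]_{control}}{[ERKPP]_{treated}}.$$

Two implementation choices deserve explanation:

* **Dynamic ratio.** `[ERKPP]_treated` is read from the current state at
  every solver step (with `[ERKPP]_control` the pre-treatment equilibrium
  level), rather than frozen at the readout time. The two readings give
  the same answer once the fast phospho-layer has settled (minutes), and
  the dynamic form behaves sensibly during the transient.
* **Transcription dependence.** The destabilization acts through the
  transcription of an intermediary gene (a miRNA or RNA-binding protein
  left out of mechanistic scope), so the modifier is conditional on active
  transcription: under actinomycin D (`ksynth = 0`) it is off by default
  (`actd_blocks_destabilization = TRUE`). That reproduces the rescue
  observation — Act D plus MEK inhibitor leaves CCND1 where Act D alone
  leaves it — and the flag's off-position lets the counterfactual be
  simulated.
* **Guard.** The ratio is capped when treated ERKPP falls below 1e-6 of
  control (with a warning) so near-total ERK inhibition cannot produce an
  unbounded degradation rate.

## Genotypes and inhibitors

Mutation directives transform the model before equilibration:

* `constitutive_activation` zeroes the rate constants of every catalytic
  process that inactivates the target's active form (annotated per
  moiety). This is implemented as rate-zeroing rather than concentration
  clamping because it preserves moiety conservation and it decouples the
  active form from upstream input — the test suite verifies that under
  constitutive KRAS, receptor-level inhibition no longer moves ERKPP.
* `null`, `partial_loss(fraction)` and `overexpression(fold)` rescale the
  target pool relative to the model's *baseline* concentrations, which
  makes genotype application idempotent.

Bundled presets encode the two cell lines used for verification: HCT116
(constitutively active KRAS, β-Catenin and PI3K; PTEN at 60% of its
physiological level; null E-Cadherin and TGF-β receptor II) and HT29
(constitutively active BRAF and PI3K; null APC and SMAD4; 2× ErbB2).

Inhibitors default to **activity scaling**: the matched catalytic rate
constants are multiplied by `1 − f`. A target given as a species scales
all catalysis by that enzyme (a basic-protein target also matches enzymes
containing it, so a GSK3β inhibitor reaches the destruction complex); a
target given as a reaction id scales that process alone. The bundled
Perifosine preset targets the AKT-activation process (PIP3-mediated
phosphorylation) rather than AKT's downstream activity, matching both its
real mechanism (it blocks AKT membrane recruitment) and the fact that its
measured endpoint is the pAKT/AKT ratio itself. **Competitive binding** is
available as the alternative mechanism: an inhibitor species plus a
sequestering reversible reaction with `koff/kon = Ki`. The Tankyrase
inhibitor XAV939 works indirectly: scaling Tankyrase-mediated Axin
turnover raises Axin, hence the destruction complex, hence β-Catenin
phosphorylation — WNT-arm inhibition without touching the WNT species
directly.

`calibrate_inhibitor()` turns a stated inhibition level into a strength:
it bisects the activity-scaling strength until the normalized readout at
the readout time equals `1 − f_desired` (bracketing is checked first; an
insensitive readout raises a calibration error rather than returning a
boundary value). The bundled levels that are calibrated this way are
CI1040 at 80% ppERK/ERK and Perifosine at 40%/70% pAKT/AKT (20 nM/40 nM
presets). The PI103, XAV939 and Azakenpaullone preset strengths (0.75,
0.80, 0.50) are package defaults chosen once to give clearly visible but
submaximal pathway inhibition in the toy network; their wet inhibition
levels are not fixed by the printed record.

## Numerical choices

* **Solver.** Stiff-capable `deSolve::lsoda` everywhere: the networks mix
  sub-second binding, minute-scale phosphorylation cycles and multi-hour
  transcript dynamics. Default tolerances `rel_tol = abs_tol = 1e-8`; the
  suite checks that halving `rel_tol` moves 30-min endpoints by far less
  than 0.1%.
* **Quasi-stationarity** is operationalized as the scaled derivative norm
  `max_i |dx_i/dt|/(abs_tol + |x_i|) < 1e-8` (per second), evaluated on
  expanding integration chunks with a hard cap of 1e7 s. Reaching the cap
  returns the state with a warning flag; a norm still growing at the cap
  raises a non-convergence error. Equilibration includes the mRNA species
  by default (they are part of the baseline); `freeze_mrna = TRUE` holds
  them fixed.
* **Negative underflow** is clipped to zero only in returned trajectories
  and in the concentrations handed to the promoter factors; solver state
  is untouched.
* **Spearman statistics.** rho is the Pearson correlation of midranks
  (tie convention); the p-value uses the exact null distribution for
  small untied samples and the t approximation with ties; the confidence
  interval is Fisher-z with standard error `1/sqrt(n−3)`. Log-linear R²
  uses natural logs (the value is base-invariant). Replicates enter as
  separate pairs sharing one simulated prediction per condition.
* **Degenerate inputs.** Constant readout vectors make rho undefined and
  raise an error; nonpositive values are rejected by the log-linear
  regression with the offending rows named; endpoints whose vehicle
  control is zero are flagged `undefined` in the readout table rather
  than silently dropped.

## What the toy generator emulates — and what it does not

`make_toy_mim()` builds a deterministic ~60-species miniature of the
three-pathway architecture: an EGF receptor layer (EGF:EGFR dimer and an
EGFR:ErbB2 heterodimer that drives PI3K, giving the HT29 ErbB2
overexpression a functional route), the KRAS→BRAF→MEK→ERK cascade with
double ERK phosphorylation and an optional ERK→receptor negative
feedback, the PI3K/PIP3/AKT arm opposed by PTEN with an AKT→GSK3β link
into the WNT arm, the Axin:GSK3β:APC destruction complex with
Tankyrase-controlled Axin turnover and E-Cadherin sequestration of
β-Catenin, a TGF-β/SMAD arm, and the TF species feeding all five promoter
sites. All parameters live in `toy_parameters()` — the fixture manifest —
not in the generator logic. The defaults were chosen once so that the
untreated equilibrium sits mid-range (ppERK/ERK and pAKT/AKT between 30%
and 60%, `P(RNAPbound) ≈ 0.5`), leaving room to move in both directions,
and so that the qualitative signatures hold: constitutive KRAS/BRAF makes
ERKPP insensitive to receptor-level inhibition, and MEK inhibition lowers
MYC faster than CCND1 at 4 h while CCND1 inhibition deepens from 4 h to
8 h.

`make_pseudo_experiments()` multiplies each simulated readout by lognormal
noise with median 1 and a stated coefficient of variation, two replicates
by default — matching the positivity of relative-expression measurements
and the log-transform used downstream.

What passing tests on this fixture do **not** show: the toy is two orders
of magnitude smaller than a realistically parameterized network (a few
dozen species against several hundred), its rate constants are uniform
rather than literature-trained, wet noise is not purely multiplicative or
independent across conditions, and mRNA readouts are taken as
instantaneous levels at the stated times (4 h and 8 h), not incubation
averages. Recovery of strong simulated-vs-pseudo-experimental correlation
at low noise demonstrates that the *pipeline* is coherent end to end, not
that any particular biological network is correctly parameterized.

## Problem sizes and runtimes

The shipped tests equilibrate the toy network (about 2e6 s of model time
per equilibration, a fraction of a second of wall time), run 30-min and
8-h treatment simulations, and perform bisection calibrations of 10–20
simulations each; the full suite and the acceptance script each complete
in well under a minute on a single core. The SBML writer is cross-checked
against an independent Python/scipy integrator on a small mixed-kinetics
model to 1e-4 relative tolerance.

## Known limitations

* No stochastic (SSA) or spatial simulation; deterministic well-mixed
  kinetics only.
* No parameter estimation: rate constants are inputs, not fitted.
* The mechanistic route of the CCND1 destabilization (miRNA/Ago) is
  represented only by the empirical degradation-rate modifier.
* SBML support covers the mass-action / Michaelis–Menten subset the
  package generates (plus compositions and roles in annotations); models
  with arbitrary kinetic-law MathML are out of scope.
* Pharmacokinetics, inhibitor off-target effects and resistance evolution
  are out of scope; an inhibitor is a static model transformation.
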