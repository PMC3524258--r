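---
title: "Transient lipid rafts and protection from dephosphorylation in early FcERI signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient lipid rafts and protection from dephosphorylation in early FcERI signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(raftsig)
```

## The scientific question

Lipid rafts are thought to shelter raft-resident signaling proteins from
transmembrane protein tyrosine phosphatases (PTPases), which partition
poorly into ordered membrane domains. Hapten-inhibition experiments in
RBL-2H3 cells appear to contradict this: after excess monovalent hapten
breaks up IgE-receptor (FcERI) aggregates, the raft-resident scaffold LAT
and the (then) nonraft receptor dephosphorylate at similar rates. `raftsig`
implements a compartmental kinetic model in which rafts are *transient* —
they form and dissolve with a mean lifetime `lambda` while their total
number stays constant — and asks whether strong raft protection is
compatible with the observed similar decay kinetics. Because a protected
protein finds itself in the nonraft membrane every time its raft dissolves,
even absolute protection (`alpha = 0`) yields finite dephosphorylation.

## Model structure

The chemistry extends the membrane-proximal FcERI network of Faeder et
al. (2003): a bivalent ligand binds and crosslinks receptors into dimers;
constitutively associated Lyn trans-phosphorylates the partner receptor's
beta and gamma ITAMs; Lyn-SH2 binds phospho-beta and Syk binds
phospho-gamma; Lyn phosphorylates the linker of partner-bound Syk and Syk
trans-autophosphorylates the partner Syk's activation loop; receptor-bound,
activation-loop-phosphorylated Syk phosphorylates LAT through an effective
Michaelis-Menten rate law; Grb2 binds phospho-LAT. An SH2-occupied
phosphotyrosine cannot be dephosphorylated; every *naked* membrane
phosphosite dephosphorylates at `k_dephos = 20`/s (naked-ITAM lifetime
0.05 s or less), scaled by `alpha` inside rafts. Syk's own phosphosites
dephosphorylate only on free cytosolic Syk, so receptor-bound Syk decays
through dissociation; this choice reproduces both the seconds-scale,
raft-insensitive Syk dephosphorylation kinetics and — exactly — the
published network size (348 receptor-containing species and 3,447
unidirectional reactions in the stimulation-phase chemistry; the
monovalent hapten adds 24 receptor species).

The membrane is two well-mixed pools. Every membrane complex class has an
equilibrium raft fraction `rho` (non-aggregated receptors 0.30, the raft
area fraction; aggregated receptors, Lyn and LAT 0.85, the zero-detergent
extrapolation of the Triton X-100 series); whole complexes exchange as
units, leaving rafts at `1/lambda` and entering at
`k+N = rho/(lambda (1 - rho))`, the rate implied by requiring the
equilibrium fraction to equal the fraction of time spent in rafts.
Membrane-membrane association is concentrated by co-confinement (rates
scaled by the inverse compartment area fraction; `scale_bimolecular`
disables this for sensitivity checks), and Lyn's catalytic rates are
5-fold lower outside rafts.

```{r}
net <- generate_network(build_model(default_params()))
network_size(net)
```

## Raft biophysics

`raft_geometry()` derives the raft count `round(coverage * A / (pi s^2))`
(about 8,000 rafts of 100 nm radius on an 8e-6 cm^2 cell at 30% coverage,
i.e. ~3.5 active Lyn per raft; the cell area is back-computed from those
printed figures). Each raft owns an annular nonraft region of outer radius
`b = 1/sqrt(pi N)`.

`diffusion_limited_rate()` implements the two-dimensional diffusion limit
for capture by *transient* disk traps, after the coated-pit formulation of
Goldstein, Griego and Wofsy (1984). When a raft dissolves, a new one forms
elsewhere, renewing the protein's position; the probability `u(r)` of
capture before an exponential turnover solves `D grad^2 u = u/lambda` with
`u(s) = 1`, `u'(b) = 0`, a closed form in modified Bessel functions `I_n`,
`K_n` of argument scaled by `1/sqrt(D lambda)`. Averaging `u` uniformly
over the annulus (the protein starts in the nonraft region) gives the mean
capture time `T = (1 - u) lambda / u` and `k+diff = 1/(T N)`. The raft
diffusion coefficient (1e-8 cm^2/s) dominates protein diffusion, so one
limit applies to all membrane proteins. The closed form is validated in
the test suite against an independent finite-difference solution of the
same boundary-value problem and against the permanent-trap mean
first-passage closed form.

Because the required entry rate grows as `lambda` shrinks at fixed `rho`,
there is a minimum physically consistent raft lifetime where it meets the
diffusion limit; equivalently `lambda_min` solves `u(lambda) = rho`. At
the default geometry this gives ~0.017 s, and — since `u` depends only on
`s/b` and `s^2/(D lambda)` — exactly 100-fold more (~1.7 s) for 1000 nm
rafts, between the two printed companion values (~1.5 and ~2.0 s). Note
one arithmetic inconsistency in the published description: ~250 rafts per
cell is quoted for 1000 nm rafts, but `0.3 * 8e-6 / (pi * (1e-4)^2)` is
~76; `raft_count()` implements the formula and the acceptance test against
the quoted 250 is left failing by design.

```{r}
raft_report(default_params())
min_raft_lifetime(raft_geometry(default_params()), 0.85, 1e-8)
```

## Parameters: units, defaults, provenance

Copy numbers are per cell (receptor 4e5, active Lyn 2.8e4, Syk 4e5);
bath ligand and hapten are molar and never depleted, with association
constants per molar per second; membrane association constants are per
(molecule/cell) per second. The full set with provenance comments ships as
`inst/extdata/params_default.yaml`.

The base-model supplement tabulating every rate constant is not machine
readable in our source text, so constants the text does not print were
transcribed by anchoring to printed quantities, chosen once and frozen:

* `koff_lyn_sh2 = 0.12`/s and `koff_syk = 0.13` (or the 35%-reduced
  lifetime, `0.2`/s, the default here) reproduce the published
  phospho-beta and phospho-gamma half-lives of ~6 s and ~11 s;
* the ligand constants put the aggregation optimum near 5 nM and make
  hapten-induced disaggregation faster than those half-lives (per-bond
  dissociation 0.5/s);
* the Lyn trans-phosphorylation scale (`p_beta_u = 0.3`, `p_beta_s = 0.9`)
  and `kon_lyn_sh2 = 2e-5` keep steady-state phospho-beta within Lyn's
  protective capacity — the regime in which the ~6 s half-life is
  insensitive to `alpha >= 0.1`, as observed;
* LAT and Grb2 copy numbers (1e6 each), the Syk->LAT Michaelis-Menten
  constants (`kcat_lat = 1`/s, `km_lat = 1e6` molecules) and the Grb2
  kinetics place LAT in the published high-phosphorylation,
  strongly-protected regime.

Consequences of this surrogate parameterization are reported honestly by
the acceptance suite: the dose-response fold changes for gamma and LAT and
the hapten-inhibition kinetics match the published values, while the
beta and Syk fold changes and the Lyn-mutation percentages agree in
direction but not magnitude (beta's no-protection phosphorylation level,
the saturation of the Syk trans-autophosphorylation loop and the
near-saturation of gamma phosphorylation — which mutes the effect of
relocating Lyn — are controlled by constants the text does not print).
Those blocks are expected to fail and say so in their messages.

## Numerical choices

The ODE system (757 states at defaults: 376 membrane complexes in two
locations plus cytosolic species) is integrated with `deSolve::lsoda`
using an analytically assembled dense Jacobian; absolute tolerance is
1e-3 molecules/cell (abundances span 1 to 1e6) and relative tolerance
1e-8. Steady state is declared when the relative derivative norm
`||dx/dt||/||x||` falls below 1e-8/s (horizon capped at 1e4 s;
non-convergence is flagged, not thrown). Conservation of each protein
total holds to machine precision structurally (checked to 1e-6 in tests).
Half-lives interpolate the first 0.5 crossing log-linearly. The
`lambda_min` root search brackets log-spaced lifetimes in [1e-4, 1e3] s.
Every accepted configuration asserts `k+ <= k+diff` at network build time.

Experiment drivers enumerate the chemistry once and re-expand it per
condition, since `alpha`, `lambda` and the partition coefficients only
enter the compartmental expansion. Problem sizes in the tests (time grids
to 180 s, dose grid evaluated at the point nearest the 5 nM optimum,
50 recovery replicates) keep the full suite at desk scale on one CPU.

## Synthetic data and what passing tests show

`generate_dephos_dataset()` emulates densitometry of hapten-inhibition
immunoblots: the model's normalized receptor and LAT decay curves sampled
at discrete times under multiplicative lognormal mean-one noise (default
CV 0.10; immunoblot noise is ratio-scale). `fit_alpha()` is a grid search
over `alpha` minimizing pooled squared residuals — mirroring discrete
curve comparison rather than continuous optimization, deliberately, since
the scientific claim is a choice among protection regimes. The generator
does not emulate receptor internalization, multivalent antigens, raft
formation kinetics, or day-to-day blot normalization drift; recovery
results therefore demonstrate identifiability of `alpha` within this
model family, not against arbitrary real data.

## Known limitations

Aggregates are capped at dimers (bivalent ligand); there is no receptor
internalization or down-regulation, no explicit Lyn activation-loop
regulation (the 5-fold nonraft activity factor is its surrogate), no raft
size distribution, and no stochastic simulation. The counting convention
for the published "348 protein species" (receptor-containing complexes of
the stimulation phase) is a reconstruction, documented in
`network_size()`.
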