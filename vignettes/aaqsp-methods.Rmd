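---
title: "Methods: coupled PBPK/PD simulation of COX-2 and 5-LOX inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled PBPK/PD simulation of COX-2 and 5-LOX inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aaqsp` couples whole-body pharmacokinetics of anti-inflammatory drugs to a
cellular model of arachidonic-acid metabolism, scores the resulting
suppression of inflammatory mediators, and propagates a rifampicin
drug-drug interaction through the same chain.  This vignette documents the
models, the assumptions behind them, and the numerical and design choices a
maintainer would want to know.

## The reduced whole-body PBPK model

Each drug is simulated over a fixed compartment graph parameterised for a
73 kg adult: arterial plasma, venous plasma, venous blood cells, gut lumen,
gut wall, a liver split into vascular / interstitial / intracellular
sub-compartments, kidney, and a lumped periphery.  Distribution is
perfusion-limited with plasma-referenced partition coefficients $K_p$;
amounts $A_i$ (µmol) evolve as

$$\frac{dA_i}{dt} = Q_i\!\left(C_{art} - \frac{C_i}{K_{p,i}}\right) + \text{(processes)},$$

with plasma flows $Q_i$ (L/min).  Oral doses enter the gut lumen and are
absorbed first-order (rate $k_a$, lag time) into the gut wall, whose
outflow is the portal inflow of the liver — so first-pass extraction is a
structural property, not a fitted bioavailability factor.  The liver
sub-compartments and the venous plasma/blood-cell pair exchange through
permeability–surface products (2 and 1 L/min by default), fast enough to
act as near-equilibrium partitioning while keeping every pool an explicit
mass-conserving state.

ADME processes attach to compartments: Michaelis–Menten metabolism
(`kcat × enzyme_scale × expression × C_u/(K_m + C_u)`, driven by the
unbound concentration), first-order renal/hepatic/biliary clearances, and
first-order transport between named compartments.  Enzyme expression is a
physiology property (liver-normalised; the defaults express CYPs/UGTs in
the liver with a small CYP3A4/UGT2B7 gut-wall contribution and zero
elsewhere — conservative, and consistent with liver-dominated first-pass
interaction), so scaling a kcat for CYP induction automatically reaches
every compartment expressing that enzyme.

Internal units are µmol, µmol/L and minutes everywhere; conversion to
ng/ml and hours happens only in `pk_metrics()` via the molecular weight.
Mass balance — moles in all compartments plus cumulative eliminated moles
equal administered moles — is checked to better than $10^{-6}$ relative
error in the test suite, and each metabolism process carries a formation
accumulator state so metabolite bookkeeping can be asserted exactly.

### Numerical contract

`deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`, dense output at 1-min
resolution (2 min for long multi-day runs).  Doses are state
discontinuities implemented through solver events (integration restarts
with state jumps); event times are merged into the output grid.  AUC(0→∞)
is trapezoid to the last point plus $C_{last}/\lambda_z$ with $\lambda_z$
fitted log-linearly on the terminal quarter of the profile; extrapolation
is refused (and flagged) when the terminal phase does not decay.

### Drug parameterisation

The packaged five drug configurations (diclofenac, celecoxib, zileuton,
licofelone, rifampicin, with their major metabolites — 32 ADME processes
in total) are produced by `scripts/calibrate.R`.  The builder fixes each
drug's structure (pathway split, metabolite tree, fraction unbound,
molecular weights) and the script tunes three knobs per drug — a joint
scale on the metabolic kcats, the periphery $K_p$, and $k_a$ — until the
simulated oral PK matches anchor values of Cmax, AUC(0→∞) and Tmax to
about 1%.  The diclofenac anchors are the 25 mg dissolved-formulation
benchmark metrics (Cmax 788 ng/ml, Tmax 0.40 h, AUC 724 ng·h/ml); the
other drugs use representative adult label/literature values (100 mg
celecoxib: 350 / 2.8 / 4500; 600 mg zileuton: 4500 / 1.7 / 25000; 200 mg
licofelone: 1700 / 2.0 / 12000; 600 mg rifampicin: 10000 / 2.0 / 60000,
ng/ml, h, ng·h/ml).  An initial licofelone Cmax guess of 2800 ng/ml was
replaced by 1700: with the AUC and Tmax anchors fixed, no physical
distribution volume can produce the larger value, and published
single-dose licofelone data sit near the smaller one.

Blood-cell partition coefficients are not identifiable from plasma PK (the
cell pool is small); they are set from lipophilicity considerations
(celecoxib 5, licofelone 3, diclofenac 1.5, zileuton and rifampicin 1).
The unbound fraction inside blood cells is assumed equal to the plasma
fraction unbound — a declared assumption, as no measured value is
available.

## The cellular network and competitive inhibition

The PD layer integrates Michaelis–Menten reaction networks with optional
feedback edges.  A reaction rate is

$$v_j(t) = V_{max,j}\, m_j(S) \frac{[S_j]}{K_{m,j}\left(1 + \sum_i I_i(t)/K_{i,i}\right) + [S_j]},$$

where the sum runs over inhibitor signals attached to the reaction's
enzyme label: competitive inhibition scales $K_m$, multiple inhibitors of
one enzyme combine additively (the standard competitive multi-inhibitor
result; the combination rule for co-treatments is this package's choice),
and $m_j$ multiplies in feedback terms
$1 + s\,\sigma R/(k_{1/2} + R)$ floored at zero.  Inhibitor
concentrations are the unbound drug levels in venous blood cells produced
by the PBPK layer (intracellular liver for rifampicin/PXR), with a 5-min
oral-cavity residence delay: the inhibition term is exactly zero until
5 min after dosing, so treated and control trajectories are identical on
that interval.

Binding affinities are fixed at
$K_{i,\mathrm{CEL,COX2}} = 0.017$, $K_{i,\mathrm{DFN,COX2}} = 0.018$,
$K_{i,\mathrm{LCF,COX2}} = 0.032$, $K_{i,\mathrm{LCF,5LOX}} = 0.056$,
$K_{i,\mathrm{ZLT,5LOX}} = 0.021$ — all in µmol/L.  The unit is an
assumption (the sources print bare numbers), consistent with the µM-scale
IC50s of these drugs; under unsaturated inhibition $K_i \approx$ IC50 by
Cheng–Prusoff.

### The packaged surrogate network

Literature leukocyte models of arachidonic-acid metabolism are distributed
as SBML and can be supplied through `load_network("sbml:<path>")`.  For a
self-contained default, `surrogate_network()` ships a reduced network:
phospholipid pool → free arachidonic acid (AA) → COX-2 branch → PGE2 and
→ 5-LOX branch → LTB4 → ω-LTB4, with enzymatic degradation of both
mediators and two feedback edges (PGE2 dampens 5-LOX; LTB4 stimulates AA
release).  "ω-LTB4" is treated as the terminal ω-oxidation product of the
5-LOX branch.  Three structural choices matter:

* **Lands-cycle re-esterification.**  Most liberated AA is re-acylated
  into phospholipids.  Without this reaction a constant release flux
  pins total steady-state branch output regardless of enzyme activity
  (inhibition only re-partitions flux), and COX-2 inhibition would even
  *raise* ω-LTB4 enough to produce negative efficacy scores.  With
  re-esterification dominating AA removal, branch fluxes respond
  near-proportionally to COX-2/5-LOX inhibition.
* **Unsaturated kinetics.**  Steady-state substrate levels (≈1–8 µM) sit
  far below every $K_m$ (30–400 µM), so the competitive factor dominates,
  matching the assumption that COX-2/5-LOX inhibition is not saturated.
* **Fast mediator turnover.**  PGE2 is degraded on the minutes scale in
  vivo; degradation capacities are set for ~10–15 min mediator
  half-lives so efficacy tracks the drug concentration with little lag.

All surrogate parameters are repository-defined, not literature values.
The network ships at its numerically determined steady state and is
additionally pre-equilibrated for 24 h before every run; the drug-free
control is always a paired simulation (identical everything except the
inhibition term), so any residual drift cancels in the score.

### SBML subset

Import/export covers an explicit SBML L3V1 subset: species with initial
concentrations and boundary conditions, single-substrate irreversible
Michaelis–Menten kinetic laws with local `Vmax`/`Km` parameters, enzyme
labels and feedback edges in a package-namespace annotation.  Any other
kinetic law raises an unsupported-construct error quoting the law.  A
network round-trips bit-identically through export + import.

## Drug efficacy score

$$\mathrm{DES}(t) = \tfrac12\left(\frac{\mathrm{PGE2}^{c}_t - \mathrm{PGE2}^{d}_t}{\mathrm{PGE2}^{c}_t} + \frac{\omega\mathrm{LTB4}^{c}_t - \omega\mathrm{LTB4}^{d}_t}{\omega\mathrm{LTB4}^{c}_t}\right)$$

against the paired control; each fractional term is ≤ 1, so DES ≤ 1, and
DES = 0 whenever treated equals control.  Scenario runs evaluate DES on a
1-min grid over 6 h and read the 0.5 h and 6 h values from the same
trajectory.  The eleven packaged scenarios (YAML, one file per row of the
therapeutic-situation registry) cover single inhibitors, co-treatments
with zileuton, rifampicin pre-treatment arms (600 mg q.d. × 7 d generic;
450 mg × 6 d and 600 mg × 5 d for the two clinical interaction studies,
whose victim doses — 100 mg diclofenac, 200 mg celecoxib — differ from the
efficacy arms and are encoded explicitly), and the correlation-study arms.

## Rifampicin → PXR → CYP induction

Intracellular unbound liver rifampicin drives a two-stage turnover
cascade: receptor occupancy $1 + (E_{max}-1)\,C/(EC_{50}+C)$ with
$EC_{50} = 1.18$ µM stimulates normalised mRNA, mRNA drives enzyme, and
the CYP3A4 activity fold is the normalised enzyme level (fold 1 without
stimulus, → $E_{max}$ under sustained saturation).  The cascade
parameterisation is configuration, with defaults $E_{max} = 8$, mRNA
half-life 6 h, enzyme half-life 36 h — chosen so a week of 600 mg q.d.
dosing approaches a stable plateau and washout decays with the enzyme
half-life.  Weaker induction of other CYPs uses increment scaling,
$f_e(t) = 1 + r_e\,(f_{3A4}(t) - 1)$ with $r_{2C9} = 0.18$,
$r_{2J2} = 0.03$, $r_{1A2} = 0.02$: of the possible readings of scaling
"analogously", this one preserves fold ≥ 1 and the ratios' meaning as
relative induction strengths (exponent scaling was the alternative; the
choice is flagged for sensitivity analysis).  CYP1A2/2J2 induction is
weak, so the zileuton/licofelone interaction path is effectively a no-op,
and their arms carry no pre-treatment.

`apply_cyp_induction()` multiplies the kcat of every metabolism process
mediated by a listed enzyme — hepatic and extrahepatic alike — and rejects
folds below 1 (inhibition is out of scope).

## Dose escalation and dose adjustment

Dose escalation reruns a scenario over a fraction grid of the therapeutic
dose; the final grid point reproduces the plain scenario bit-for-bit.
`dose_adjustment_search()` finds, by bisection on a numerically verified
monotone DES-dose relationship, the smallest multiplier of the victim dose
for which the interaction arm reaches the reference arm's DES
(|ΔDES| < 10⁻³), reporting the raw multiplier and a 0.5-step rounding.
On the surrogate network diclofenac's DES has decayed to baseline by 6 h
(its half-life is ~1 h), which would make a 6 h match degenerate; the
packaged diclofenac adjustment is therefore matched at 1 h — the initial
therapeutic efficacy the adjustment is meant to restore — while celecoxib
(flat DES profile) is matched at 6 h.

## Correlation with pain relief

`fit_hill()` fits $y = a x^b/(c^b + x^b)$ to (PGE2 decrease, pain relief
minus placebo) pairs by Levenberg–Marquardt least squares from a
deterministic multi-start grid, with seeded parametric-bootstrap 95%
confidence intervals (1000 resamples by default) and R², AIC and RMSE for
model comparison against an Emax (exponent-1) and a linear candidate.
The underlying clinical pain-relief scores are not redistributable, so
the packaged evidence is parameter recovery on synthetic data: noise-free
generation is recovered to 4 significant digits, and over 100 noisy
replicates (Gaussian noise, SD 5% of the asymptote) the bootstrap
intervals cover the true parameters ≥ 90% of the time.  Pairs are formed
over the 6 h window; a 24 h horizon is an option of the scenario configs.
Pooling of the three diclofenac dose levels into one curve is assumed.

## Synthetic data

`synth_config()` fixes everything: seeds give byte-identical output.
PK observations use proportional log-normal error
($C_{obs} = C_{true} e^{\varepsilon}$, $\varepsilon \sim N(0, CV)$), the
standard residual model for concentration data; pain scores use additive
Gaussian noise; the toy network is a source → AA → two-branch chain with
a common branch $K_m$, so its uninhibited steady state is closed-form and
under a constant competitive COX-2 inhibitor the branch balance reduces
to a quadratic solved exactly by `toy_steady_state()` — an algebraic
oracle independent of the ODE solver.  What the generators deliberately do
not emulate: inter-individual variability, absorption-model
misspecification, assay limits of quantification, and dropout — so
passing recovery tests demonstrates estimator correctness, not robustness
to real clinical data pathologies.

## Problem sizes and runtimes

The test suite runs the full scenario pipeline at 1–2 min output
resolution, the bootstrap-coverage check at 40 replicates × 200 resamples,
and the brute-force Euler oracles at 3–12 ms steps; the acceptance script
(`scripts/acceptance.R`) recomputes everything at the full sizes (100
coverage replicates, 48 h PK spans, all eleven scenarios) in a few
minutes on one CPU.

## Known limitations

* The compartment layout is reduced; organ-level predictions outside the
  compartments listed (e.g. brain, adipose) are out of scope, as are
  solid formulations, population variability and CYP2C9 genotypes.
* The surrogate network reproduces the *mechanistic shape* of the
  mediator response, not literature-network output; efficacy scores on
  the surrogate are internally consistent but not comparable in absolute
  value to scores computed on an imported literature SBML network.
* COX-1 is deliberately absent (diclofenac is treated as COX-2-selective
  in this context).
* Transport processes are first-order; saturable transporters are not
  modelled.
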