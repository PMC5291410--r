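---
title: "Non-autonomous gap gene circuits: model, analysis, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-autonomous gap gene circuits: model, analysis, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gapdyn)
```

## The model and its assumptions

`gapdyn` simulates connectionist gene-circuit models of the *Drosophila*
trunk gap gene system. The state of the model is the concentration
`g_i^a(t)` of each gap protein `a ∈ {hb, Kr, gt, kni}` in each nucleus `i`
of a one-dimensional row covering 35–92% A–P position. During interphase

$$\frac{dg_i^a}{dt} = R^a\,\phi(u_i^a) +
  D^a(n)\,\bigl(g_{i-1}^a + g_{i+1}^a - 2g_i^a\bigr) - \lambda^a g_i^a,$$

where the total regulatory input is
$u_i^a = \sum_b W_{ab}\,g_i^b + \sum_m E_{am}\,g_i^m(t) + h^a$ and
$\phi(u) = \tfrac12\bigl(u/\sqrt{u^2+1} + 1\bigr)$ is the sigmoid
regulation-expression function (bounded in (0, 1), $\phi(0) = 1/2$,
$\phi(u) + \phi(-u) = 1$). The external regulators
`m ∈ {Bcd, Cad, Tll, Hkb}` enter as time- and space-indexed concentration
profiles, not as state variables: they are parameters, and their
time-dependence is what makes the system non-autonomous.

Assumptions inherited from this model family: one spatial dimension with
nuclei as well-stirred compartments; deterministic kinetics (no
transcriptional noise, no mRNA/protein distinction); spatially uniform
factors absorbed into the thresholds `h`; zero-flux boundaries at both ends
of the row (the absent neighbour is mirrored, which conserves mass under
pure diffusion). The simulation is hybrid: production is switched off during
the C13 mitotic phase, and at the C13→C14A division the nuclei double
instantaneously, each daughter inheriting its parent's concentrations.
Diffusion uses a discrete Laplacian whose coefficient scales 4-fold per
division because the inter-nucleus distance halves
(`diffusion_coefficient`). All circuits analysed downstream are
diffusion-less (`D = 0`), which uncouples the nuclei and makes the
per-nucleus phase space four-dimensional.

## Timeline and units

The default `stage_schedule()` is: C13 interphase 16 min, C13 mitosis 4 min,
instantaneous division at 20 min, then cycle C14A lasting 50 min split into
eight equal time classes T1–T8, ending at gastrulation (70 min). The
literature's mitotic schedule is defined in data we do not ship, so these
durations are package defaults of the right magnitude, exposed as
constructor arguments. The ten phase-portrait *analysis times* are
mid-C13-interphase, the midpoints of T1–T8, and gastrulation time.
Concentrations are in arbitrary units (au) with no hard cap; positions are
%A–P (0% = anterior pole); rates are per minute.

## Simulation

`simulate_circuit()` integrates the hybrid system with an adaptive embedded
Cash–Karp Runge–Kutta (4/5) stepper implemented in compiled code, restarting
cleanly at phase boundaries and at the division (no smoothing across the
event). Default tolerances are `rtol = 1e-8`, `atol = 1e-10`; model fitting
uses `1e-6`/`1e-8`, which changes final states by far less than the
observation noise. External inputs are interpolated piecewise-linearly in
time between profile knots (exact at knots). In the test suite the stepper
is cross-checked against an independent `deSolve::lsoda` integration of the
same right-hand side.

Frozen-gradient runs (`mode = "frozen"`) clamp the external profiles at a
chosen time — by default the earliest profile time, i.e. early blastoderm
values — turning the model autonomous from the clamp onwards. All four
external inputs are frozen by default; `freeze_species` restricts the clamp
to a subset (e.g. only the maternal Bcd/Cad). With time-constant inputs the
dynamic and frozen modes coincide, which the tests assert to 1e-8.

## Instantaneous phase portraits

For one nucleus at one time, freezing the external inputs yields an
autonomous 4D vector field whose every steady state lies in the box
`[0, R/λ]` per gene (because `0 < φ < 1`). `find_steady_states()` runs
Newton–Raphson with the analytic Jacobian
$J_{ab} = R^a \phi'(u^a) W_{ab} - \lambda^a \delta_{ab}$ from a regular grid
(5 starts per axis by default) plus 500 seeded uniform random starts;
converged roots are de-duplicated at 1e-5 of the box diagonal and roots
outside the box are discarded. The number and placement of starts, the
de-duplication radius, and the tracking rule below are package decisions:
the toy fixtures (a two-gene toggle switch and a two-gene spiral circuit
with exactly known roots and eigenvalues) plus a forward-integration oracle
pin their adequacy down in the tests.

Steady states are classified from their eigenvalues: all real parts negative
gives an attractor (spiral sink if any imaginary part exceeds 1e-8), mixed
signs a saddle, all positive an unstable node or spiral source, and any real
part within `1e-6 × max|Re|` of zero is reported as marginal.

`portrait_series()` tracks states across consecutive analysis times by
greedy nearest-neighbour matching with a maximum matching distance of 20% of
the box diagonal. Unmatched disappearances and appearances become events; a
simultaneous loss (gain) of a nearby attractor–saddle pair is labelled a
saddle-node annihilation (creation). Bifurcation timing is therefore
reported as an interval between analysis times, not an instant.

Basins are never constructed as geometric separatrices: in four dimensions
`basin_of()` decides membership pointwise, by forward-integrating the frozen
field until the trajectory comes within 1e-4 of the box diagonal of a known
attractor, or until ten times the slowest decay time (a horizon that
`classify_mechanism()` lets you extend, since trajectories crawl through the
ghost of a just-annihilated saddle-node pair).

## Mechanism classification

For each nucleus, `classify_mechanism()` evaluates the basin of the
trajectory state at every analysis time, then labels each interval:

* **topological capture** — the basin changed and a bifurcation event was
  recorded in the same interval (enforced by construction);
* **geometrical capture** — the basin changed with no bifurcation, i.e. the
  moving separatrix overtook the trajectory;
* **pursuit** — same basin, but the governing attractor moved by more than
  5% of the box diagonal;
* **transition** — same basin, attractor effectively static, trajectory
  converging.

The distinction between "transition" and slow pursuit is qualitative in the
narrative literature; the 5% displacement threshold is this package's
operationalisation. Unresolved basins propagate as "unclassifiable"
intervals rather than errors.

## Pattern features

Domains are contiguous runs above half of the profile's own maximum
(per gene, per time — scale-free), with boundary positions interpolated
linearly between the flanking nuclei and domains narrower than two nuclei
discarded as speckles. Boundary time courses link domains across times by
nearest position; `shift_rate()` reports per-interval finite differences and
the least-squares slope (negative = anterior-ward); `overshoot()` reports
the signed frozen-minus-dynamic boundary difference, negative when the
frozen-run boundary lies further anterior.

## Reverse engineering

`fit_circuit()` fits the weights `W`, `E` and thresholds `h` (production,
decay and diffusion rates are held fixed) by minimising the weighted
least-squares cost with serial simulated annealing: geometric cooling,
one-coordinate Gaussian proposals reflected at the box bounds and at zero
for sign-constrained coordinates (so no proposal ever violates the
constraint set), and step sizes adapted toward 44% acceptance. Weights
default to uniform; a per-observation `weight` column is honoured.
"Numerically unstable" is operationalised as solver step failure, a step
budget overrun, or any non-finite state; such simulations cost a large
sentinel instead of raising, so the optimizer can leave the region. For
diffusion-less circuits the nuclei are uncoupled, so fitting on a coarser
row (`coarse_rows()`) is exact and proportionally faster; the shipped
recovery protocol fits 14 C13 / 28 C14A nuclei.

`select_circuits()` applies the selection cascade: discard unstable
circuits, discard RMS ≥ 20.0, discard circuits with any automated defect
flag, discard circuits whose posterior domains do not shift anterior-ward by
at least one inter-nucleus spacing between T1 and T8, and rank by RMS. The
defect detectors are quantitative stand-ins for visual screening: a missing
domain (model < 20% of the data maximum in the expected window), a bimodal
domain (two local maxima with a trough below half the lower peak), and a
disconnected boundary (a flank that re-crosses the half-maximum level
without qualifying as bimodal — the two flags are deliberately mutually
exclusive so each fixture triggers exactly one).

`recovery_experiment()` is the scaled-down stand-in for large parallel
annealing protocols: ten serial chains of 16,000 proposals each (a few
minutes on one CPU) instead of hundreds of multi-core runs. Equivalence to
any particular annealer is statistical, not bitwise.

## The synthetic data generator

Real quantified expression profiles are not bundled; `synthetic_config()`
defines parametric stand-ins chosen to emulate their qualitative structure:

* **Bcd**: `A(t)·exp(−x/20%)`, amplitude 100 au, constant until the start of
  T3 and then decaying linearly to 40% by gastrulation;
* **Cad**: a posterior sigmoid (edge 45%, steepness 2.5%) with a gentle
  posterior-increasing ramp across the trunk (tilt 0.45, mimicking the
  graded trunk profile of the real posterior gradient); from the start of T3
  the level decays linearly to 45% and the anterior edge retreats 10%
  posteriorly — monotone non-increasing in time everywhere posterior of the
  initial edge;
* **Tll / Hkb**: Gaussian posterior domains (centres 85% and 92%, widths 3%
  and 2.5%, amplitude 80 au), negligible anterior of 75% so the 35–71%
  analysis range is free of terminal inputs;
* **maternal Hb**: an anterior step (60 au, edge 47%) as the initial
  condition; the other genes start at zero;
* **noise**: truncated-at-zero Gaussian with SD 2% of each species' maximum,
  seeded.

The ground-truth circuit (`ground_truth_params()`) follows the consensus
sign structure of the trunk network: activation by Bcd and Cad, repression
by the terminal genes, weak self-activation, strong mutual repression
between the mutually exclusive pairs hb/kni and Kr/gt, and asymmetric
repression in which each gene is repressed strongly by its posterior
neighbour. The one-way Kr → kni → gt repression cycle is an odd negative
feedback loop, so posterior nuclei carry a damped oscillation — most
instantaneous portraits posterior of ~55% are monostable spiral sinks, and
the temporal gene succession it drives produces anterior-ward domain shifts
without diffusion. Rate constants (`R = 15` au/min, `λ = 0.095`/min, so a
~10 min protein half-life and a 158 au concentration ceiling) put the
system in the regime where the spiral is clearly damped yet the shifts
remain visible within the 50 min of C14A.

Generation verifies its own contract and fails loudly otherwise: at least
four distinguishable domains at T4, and posterior kni and gt domains whose
anterior boundaries move anterior-ward by more than one nucleus spacing
between T1 and T8.

What the generator does *not* emulate: embryo-to-embryo variability,
nuclear-level measurement error structure, the exact clearing kinetics of
the real posterior gradient, and the anterior head domains outside
35–92%. Two known cosmetic limitations of the default circuit: domain
amplitudes fade towards gastrulation more strongly than real data do, which
blurs half-maximum boundaries after ~T5 (the posterior kni boundary
backtracks slightly once its domain fades), and nuclei posterior of ~63%
pass through a brief early window in which the instantaneous portrait is an
unstable spiral surrounded by a small limit cycle before the sink stabilises.
Passing tests on these synthetic conditions therefore demonstrate that the
machinery measures what it claims on data with the assumed structure — not
that any particular biological estimate is reproduced.

## Numerical choices and degenerate inputs

* Solver: Cash–Karp 4/5 with step-size control `0.9·err^(−1/5)` (accept) and
  `0.9·err^(−1/4)` (reject), clamped to [0.1, 5]; failure at the minimal
  step flags the run unstable rather than erroring.
* Newton steps are capped at one box diagonal to keep iterates near the
  positively invariant box; non-convergent starts are dropped and counted.
* A zero-size box (all `R = 0`) degenerates gracefully: the origin is the
  unique root.
* Ties in nearest-neighbour tracking resolve to the smallest distance first
  (greedy); matching is capped at 20% of the box diagonal.
* All-zero expression profiles yield zero domains, not errors; boundary
  linking across times tolerates missing domains as gaps.

## Problem sizes

The shipped analyses use the full 58-nucleus row for simulation and feature
extraction, 19 nuclei at 2% spacing for the portrait/mechanism scan
(35–71%), 4 grid starts per axis plus 200 random starts per portrait during
the scan (5 plus 500 for the reference searches in the tests), and ten
16,000-proposal annealing chains for the recovery experiment. These sizes
were chosen so the whole pipeline — generation, both simulation modes,
portrait scan, mechanism classification, and recovery — completes on a
single CPU in well under an hour while leaving every qualitative conclusion
unchanged under doubling.
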