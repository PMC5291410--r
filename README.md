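# gapdyn

Simulation and non-autonomous phase-space analysis of gap gene circuits in
the early *Drosophila* blastoderm.

## The problem

The trunk gap genes *hunchback* (*hb*), *Krüppel* (*Kr*), *giant* (*gt*) and
*knirps* (*kni*) are patterned by the maternal morphogen gradients Bicoid
(Bcd) and Caudal (Cad) and by the terminal factors Tailless (Tll) and
Huckebein (Hkb). The maternal gradients are not static: Bcd decays and Cad
clears from the trunk on the same time-scale on which the gap pattern forms,
so the regulatory system is *non-autonomous* — its effective parameters
change while it runs. `gapdyn` is built for studying exactly this: what the
time-dependence of the inputs does to gap gene expression levels, to the
anterior-ward shifts of the posterior gap domains, and to the phase-space
structures (attractors, saddles, basins, bifurcations) that steer each
nucleus.

## The model

Each nucleus `i` carries concentrations `g_i^a` of the four gap proteins.
During interphase,

    dg_i^a/dt = R^a φ(u_i^a) + D^a(n) (g_{i-1}^a + g_{i+1}^a − 2 g_i^a) − λ^a g_i^a
    u_i^a     = Σ_b W_ab g_i^b + Σ_m E_am g_i^m(t) + h^a
    φ(u)      = ½ (u / √(u² + 1) + 1)

with production rates `R`, diffusion `D` (scaling 4-fold per cleavage
division; zero in the circuits analysed here), decay rates `λ`, gene–gene
weights `W`, external-input weights `E` over `m ∈ {Bcd, Cad, Tll, Hkb}`, and
thresholds `h`. Production is switched off during mitosis, and the nuclei
double at the C13→C14A division with daughters inheriting their parent's
state. The external concentrations `g^m(t)` are interpolated input profiles
— the time-dependent parameters that make the system non-autonomous.

On top of the simulator the package provides:

* **frozen-gradient runs** — the same circuit with inputs clamped at their
  early values, isolating the effect of gradient decay (`simulate_circuit`
  with `mode = "frozen"`, `compare_runs`);
* **instantaneous phase portraits** — per nucleus and time point, all steady
  states of the diffusion-less 4D system by Newton–Raphson with analytic
  Jacobians, classified by their eigenvalues (point attractor, spiral sink,
  saddle, ...), tracked over time, with saddle-node bifurcations detected
  (`instantaneous_field`, `find_steady_states`, `portrait_series`);
* **mechanism classification** — each inter-analysis interval of a nucleus'
  trajectory labelled as transition, pursuit, geometrical capture, or
  topological capture from its basin history (`classify_mechanism`);
* **pattern features** — half-maximum domain boundaries, boundary time
  courses, shift rates, frozen-run overshoot (`extract_domains`,
  `boundary_timecourse`, `shift_rate`, `overshoot`);
* **reverse engineering** — weighted least-squares fitting by
  sign-constrained simulated annealing, defect detection, and the selection
  cascade (`fit_circuit`, `anneal`, `detect_defects`, `select_circuits`);
* **a synthetic-data generator** — parametric stand-ins for the quantified
  input gradients and a ground-truth circuit whose posterior domains shift
  anterior-ward (`synthetic_config`, `ground_truth_dataset`), so the whole
  pipeline runs without external data.

## Worked example

```r
library(gapdyn)

cfg <- synthetic_config(seed = 1)
gt  <- ground_truth_dataset(cfg)          # inputs + noisy expression data
frz <- simulate_circuit(gt$params, cfg$schedule, gt$profiles, gt$init,
                        mode = "frozen")  # gradients clamped at t = 0

at <- cfg$schedule$analysis_times
bd <- boundary_timecourse(gt$trajectory, "gt", side = "anterior", times = at)
b  <- bd[bd$domain == 1 & bd$time >= at[["T1"]] & bd$time <= at[["T8"]], ]
round(b$position, 1)
#> [1] 66.5 64.3 63.4 62.2 60.3 58.4 56.8 56.1
round(shift_rate(b)$intervals$rate[c(1, 7)], 3)
#> [1] -0.338 -0.108
ov <- overshoot(bd, boundary_timecourse(frz, "gt", "anterior", times = at))
ov$table[abs(ov$table$time - at[["T8"]]) < 1e-9, ]
#>     time  dynamic   frozen difference
#> 9 66.875 56.13006 54.73293  -1.397126
```

The posterior *gt* domain's anterior boundary moves ~10% A–P toward the
anterior between time classes T1 and T8, and the per-interval shift rate
falls about three-fold as the maternal gradients decay. In the frozen run
the same boundary at T8 sits 1.4% *further anterior* than in the dynamic run
— the overshoot that gradient decay normally reins in.

The `analysis/` directory contains the numbered drivers that reproduce the
full study on the synthetic conditions: `01_synthesize_data.R`,
`02_frozen_vs_dynamic.R`, `03_phase_portraits.R`, `04_mechanisms.R`,
`05_fit_recovery.R`. Each writes its tables and a run manifest under
`results/`.

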