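# boolpop

Continuous-time stochastic Boolean networks with cell-population dynamics,
built to study how immunogenic cell death (ICD) of tumour cells mounts an
adaptive antitumour immune response — and which molecular knobs strengthen
it. It is aimed at systems biologists who work with logical (Boolean)
models of signalling and cell–cell communication and want population-level
readouts (cell counts over time, knock-out effects, parameter scans)
without leaving R.

## The model class

A *rate-annotated Boolean network* assigns each node `i` two expressions
over the network state `x` and named `$`-parameters: an activation rate
`r_up_i(x)` (used while `x_i = 0`) and a deactivation rate `r_down_i(x)`
(while `x_i = 1`), in 1/h. This defines a continuous-time Markov jump
process on the 2^N Boolean states: from `x`, the waiting time is
`Exponential(R)` with `R = Σ_i r_i(x)`, and node `i` flips with probability
`r_i/R`. The engine samples exact Gillespie trajectories (a C++ kernel with
incremental rate updates and per-trajectory RNG streams) and estimates
node/state probability curves by Monte Carlo; a pure-R master-equation
oracle (`exact_transient()`, matrix exponential of the full generator)
validates it on small networks.

Populations are built on top: a state distribution times a scalar size
factor is a cell population. Every `dt` hours the simulation is stopped,
cells with Death = 1 are removed, cells with Division = 1 are doubled
(Division reset), the size factor is multiplied by `1 − P(Death) +
P(Division)`, and *population-updated parameters* — typically receptor
activation rates proportional to the population probability of their
ligand — are recomputed. This mean-field ligand–receptor coupling is what
lets non-interacting single-cell trajectories describe an interacting
population.

Models are defined in code (`bp_network()`) or in a three-file text dialect
(`.bnd` logic/rates, `.cfg` parameters/initial condition/settings, `.upp`
Death/Division declarations and update rules) via `parse_model()` /
`write_model()`; both shipped ICD models are also installed as files under
`inst/extdata/models/`.

## Shipped ICD models

* `build_phenomenological()` — 13 nodes, 19 parameters (5
  population-updated): treated tumour cells expose CALR/ATP (4 h) and HMGB1
  (6 h); dendritic cells sense them, activate, and reach the lymph node
  after ~5 days; primed T cells become CTLs in 2 days and clear the tumour
  at about 220 h.
* `build_extended()` — 57 entities, 98 parameters (20 population-updated):
  explicit DAMP/receptor pairs, DC maturation, CD28/TCR co-stimulation,
  Th1/Th2/Th17/Treg differentiation, IL-2/IFNγ-dependent CTL formation, and
  perforin-mediated killing.
* `apply_scenario()` — reversible interventions: `cd28_ko`,
  `il2_treatment`, `no_clonal_expansion`.
* `make_variants()` / `run_scan()` / `rank_effects()` — single-parameter
  sensitivity scans (More = ×f, Less = ÷f) with tumour-size readouts.

## Worked example

```r
library(boolpop)
model <- build_phenomenological()
model
#> Boolean network: 13 nodes, 19 parameters, 5 population-updated
#>   death node: Death; division node: Division
#>   8 cell-type predicates; settings: time_step=2, horizon=300

tc <- run_icd(model, n_traj = 5000, seed = 1)   # 150 windows of 2 h
s <- summarize_celltypes(tc)
s$readouts
#>    celltype initial   final peak_time clearance_time
#>       Tumor     0.8 0.00000         2            214
#>  DyingTumor     0.0 0.00000         8             NA
#>          DC     0.1 0.09996       114             NA
#>       ActDC     0.0 0.09996       114             NA
#>      MigrDC     0.0 0.09863       300             NA
#>     LNodeDC     0.0 0.09416       300             NA
#>       TCell     0.0 0.00676       204             NA
#>         CTL     0.0 0.03360       262             NA
```

Curves are absolute cell counts relative to an initial population of 1:
the tumour compartment (initially 0.8) is cleared — first drops below 1%
of its initial value — at 214 h, shortly after the T-cell compartment
peaks at 204 h; dendritic cells neither die nor divide, so their count
stays at 0.1. `s$curves` holds the tidy per-window curves, and
`write_timecourse()` exports any run to CSV/JSON.

The numbered scripts under `analysis/` run the full study: engine
validation against exact oracles (`01`), the wild-type phenomenological
and extended runs with event-timing tables (`02`, `03`), the CD28
knock-out and IL-2 interventions (`04`), and the ±50% and factor-5
sensitivity scans with effect rankings (`05`). Each writes its tables
under `results/`.

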