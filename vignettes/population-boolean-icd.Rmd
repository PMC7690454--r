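---
title: "Stochastic Boolean population modeling of immunogenic cell death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Boolean population modeling of immunogenic cell death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(boolpop)
```

## The model class

`boolpop` simulates *rate-annotated Boolean networks*: each node carries an
activation-rate expression (`rate_up`, applied while the node is 0) and a
deactivation-rate expression (`rate_down`, applied while it is 1), both in
units of 1/h and both allowed to depend on the rest of the state and on named
`$`-parameters. A network of N nodes defines a continuous-time Markov jump
process on its 2^N states: from state x, node i flips with rate r_i(x), the
waiting time is exponential with rate R(x) = sum_i r_i(x), and the flipped
node is chosen with probability r_i/R. The engine draws exact Gillespie
trajectories of this process; node- and state-probability curves are Monte
Carlo averages over trajectories, sampled at grid points.

Two conventions connect rates to the biology: a process with a reported
*mean time* T gets rate 1/T, and a species with a reported *half-life* H
gets deactivation rate ln(2)/H.

### Cell populations

A single network state is read as one cell; a probability distribution over
states, multiplied by a scalar population-size factor, is a cell population.
Population dynamics are layered on top of the jump process by alternating
free evolution over windows of length `dt` with an update phase at each
window end:

1. cells (particles) evolve independently for `dt` hours;
2. the mass on states with the Death node ON (fraction d) is removed, the
   mass on states with Division ON and Death OFF (fraction b) is doubled and
   the Division node is reset to 0 — a dead cell does not divide, so death
   takes precedence when both nodes are set;
3. the size factor is multiplied by the window ratio 1 − d + b and the
   distribution is renormalized;
4. every population-updated parameter is recomputed from the post-update
   distribution; the typical rule makes a receptor's activation rate
   proportional to the population probability of its ligand, which is how
   non-interacting single-cell trajectories are coupled into an interacting
   population (a mean-field coupling refreshed once per window).

Update rules are expressions over parameters and `p(<Boolean predicate>)`
terms (joint probabilities over the current distribution); a bare node name
inside a rule denotes its marginal ON-probability. End-of-window (not
window-averaged) probabilities feed the rules, matching the semantics of a
simulation that is stopped, edited, and restarted.

## Numerical choices

**Particle representation and resampling.** The population state is carried
as n_traj equally weighted particles. After the death/division bookkeeping
the next window's particle set is drawn by *systematic (stratified)
resampling*: one uniform offset, n evenly spaced positions over the
cumulative weights. Realized counts then deviate from n·w by less than one
particle, so with no death or division the particle set is carried over
exactly, a particle of doubled weight yields exactly two copies, and the
population composition does not random-walk over long runs. (With plain
multinomial resampling the composition drift over 150 windows is on the
order of sqrt(150/n), which at n = 2000 visibly corrupted even a static
population.)

**Random numbers.** Every trajectory owns an RNG stream seeded from the
(global seed, trajectory index) pair via a splitmix hash, so results are
reproducible bit-for-bit for a given seed and independent of evaluation
order. R-side sampling (initial conditions, resampling) uses seeds derived
deterministically from the run seed and never touches the caller's RNG
state.

**Window length.** `dt` defaults to 2 h for the shipped models (horizon
300 h, 150 windows): short against the population-level delays being
resolved (days), long against fast protein flicker (12-min degradation),
which correctly stays *within* windows. Halving or doubling `dt` moves the
landmark readouts by less than the Monte-Carlo spread.

**Curve readouts.** Probability curves are sampled at grid points (the state
at the grid time), not window-averaged. Derived times are computed on
absolute cell-count curves (probability × size factor): clearance is the
first time a curve falls below 1% of its initial value; activation times are
half-maximum crossings with linear interpolation between grid points, which
resolves events closer together than one window.

**Exact oracle.** For networks of up to 12 nodes, `exact_transient()` builds
the full 2^N × 2^N generator with R-side expression evaluation and
propagates the initial distribution with a matrix exponential
(`Matrix::expm`). It shares no code with the C++ trajectory kernel, so
engine-versus-oracle agreement (within 3/sqrt(n_traj) per state mass, about
three standard errors) is a genuine two-route check. The synthetic
benchmark generator (`make_independent_chain()`, `make_birthdeath_case()`,
`make_random_network()`) wraps closed forms, a window-discretized branching
recursion, and this oracle into self-checking cases.

## The shipped ICD models

Both models describe a mixed population — tumour cells, dendritic cells
(DCs), T cells — after an immunogenic-cell-death-inducing chemotherapy.
Cell identity is encoded in input nodes (TumorCell, DC, cd4, cd8); a cell of
one type simply never satisfies the activation guards of another type's
nodes. Hyphenated biological names are transliterated with underscores
(TCR-I becomes TCR_I; secreted ligands are `*_o`, receptors `*_rec`).

### Phenomenological model (13 nodes, 19 rate parameters)

Treated tumour cells enter a dying state (mean 1 h) and expose the danger
signals CALR and ATP (mean 4 h) and HMGB1 (6 h, the slowest). DCs sense the
summed population level of the three signals and activate; activated DCs
transit to the draining lymph node with a total mean of 5 days; lymph-node
DCs prime T cells at a rate proportional to their population level; T cells
differentiate into CTLs over 2 days; the tumour death rate is proportional
to the CTL population level, plus a "low" direct-cytotoxicity term on a
50,000 h scale. Tumour cells divide every 10 days, CTLs every 12 h (clonal
expansion). Five of the 19 parameters are population-updated sensing levels
(initially 0); 14 are set by hand. The initial population is 80% tumour,
10% DC, 10% naive T cells (the all-zero state).

Free choices that the timing constraints above leave open were fixed by
calibrating to the two kinetic landmarks the model is built to reproduce
(tumour clearance about 220 h, T-cell peak about 200 h) at the standard run size (n_traj = 5000, dt = 2 h):

* the 5-day lymph-node transit is split evenly over the two DC steps
  (1/60 + 1/60 per hour) rather than concentrated in one exponential step:
  the two-stage (Erlang-2) arrival suppresses the early lymph-node trickle,
  which otherwise seeds CTLs tens of hours too early and makes the
  clearance time run-to-run unstable;
* effector CTL turnover is set equal to the clonal-expansion rate (1/12 per
  hour), so the CTL pool tracks the T-cell conversion flux instead of
  running away exponentially; the no-clonal-expansion scenario still loses
  most of its killing capacity, reproducing the persistent-tumour contrast;
* the DC-activation scale (0.15 per unit summed signal), the priming scale
  (0.115 per unit lymph-node DC level) and the kill coefficient (0.7 per
  unit CTL level) complete the timeline.

With these defaults a 5000-particle run gives clearance at 210–240 h and a
T-cell peak at 190–225 h across seeds.

### Extended model (57 entities, 98 parameters)

The molecular refinement: four DAMPs (CALR, ATP, ANXA1, HMGB1 — HMGB1
release requires ANXA1 already present) with their DC receptors (LRP1,
P2X7R/P2Y2R, FPR1, TLR4); DC activation by extracellular ATP through P2X7R;
antigen uptake (LRP1-dependent), CCR7 and maturation markers (MHC-I/II,
CD80, CD40, CD86); type-1 interferon and CXCL10-guided homing (CXCR3);
CD28/TCR co-stimulation; CD4 lineages Th1 (IL-12), Th2 (IL-4), Th17
(IL-6 + TGFb + IL-1B), Treg (TGFb); CD8 priming to preCTL and IL-2/IFNg
dependent differentiation into CTL; and perforin-mediated tumour killing
whose rate is proportional to the population probability of
perforin-armed CTLs (scaled so an all-CTL population kills a tumour cell
in 1 h). A CTL surrounded by tumour cells loses its perforin in 6 h
(population-coupled deactivation), and dies after 10 days. Adopted rates:
protein activation 6 h (ATP/CALR 4 h), protein degradation 12 min, fast
cell-state switches 12 min, CTL activation 2.4 h, tumour division
100,000 h, chemotherapy half-life 3 days (ln 2/72 per hour), ICD induction
1 h, direct cytotoxicity 1/50,000 per hour, lymphocyte division 20 h
(`clonal_exp_rate` = 0.05). Twenty parameters are population-updated and
start at 0: the 18 receptor rates, the kill amplification, and the
perforin-loss rate. The four initial-composition parameters (80/10/5/5)
are part of the 98 and are scanned like any other manual parameter.

Where the ICD literature constrains only parts of the roster, the
remaining entities are standard members of the same pathway (tumour
antigen, the co-stimulatory molecules CD40 and CD86, TNF-alpha and its
receptor). Receptor coupling scales are this package's own choices.

**Known limitation.** With lymphocyte division at 20 h and CTL death at 10
days, the activated-lymphocyte compartment grows without bound
(~0.045/h), so any early trickle of primed CD8 cells eventually ignites
clearance: the reconstruction's tumour decay starts near 110 h and
completes near 140 h, earlier than the ~250 h onset it was designed to
show, and this
cannot be moved past ~170 h by rescaling receptor couplings alone. The
event *sequence* and every structural and parametric count match; the two
extended-model quantities checked quantitatively (chemotherapy half-life,
CD28-knock-out tumour share) do not depend on the wild-type ignition time.
Relatedly, after clearance the absolute size of the expanding lymphocyte
compartment dominates the population, so activation-time readouts are taken
on the pre-clearance epoch.

### Scenarios

`apply_scenario()` edits a model reversibly: `cd28_ko` clamps the CD28
activation rate to 0 (T-cell priming becomes structurally unreachable, so
the tumour keeps its initial 80% share — only the 50,000 h direct term
acts); `il2_treatment` drives the IL-2 ligand node everywhere at five times
its basal production rate (a constant exogenous source); and
`no_clonal_expansion` zeroes the lymphocyte division rate. In this
reconstruction exogenous IL-2 advances clearance only modestly (a few
hours), because IL-2 sensing is co-limiting with IFNg rather than the
dominant bottleneck.

## Sensitivity scans

`make_variants()` builds two variants per manually set parameter: More
multiplies by the fold factor, Less *divides* by it (the division
convention makes, e.g., 0.1/1.5 = 0.067 and 0.05/1.5 = 0.033, and keeps
More and Less exact inverses). `run_scan()` runs one population simulation per variant
with a seed derived from (scan seed, variant position), records the
absolute tumour size at the readout times, and always includes the
unperturbed WT row; `rank_effects()` orders variants by absolute deviation
from WT with lexicographic tie-breaks, so rankings are deterministic and
invariant to row order. Variant rows are independent, so large scans can be
chunked by subsetting the variant table and merged afterwards.

## Problem sizes

The shipped analyses use n_traj = 5000 and dt = 2 h over 300 h for
headline runs, 10,000 trajectories for the two single-curve estimates
(first-activation mean, decay half-life), 50,000 trajectories for
engine-versus-oracle checks on networks of up to 6 nodes, and 1000
particles per variant in the demonstration scans. At these sizes a
wild-type phenomenological run takes a few seconds and a full
engine-validation pass under half a minute on one core.

## What the synthetic benchmarks do and do not show

The generator produces networks whose transient behaviour is known exactly
(independent chains, birth–death toys, small random guarded networks), so
it can detect errors in waiting-time sampling, node selection, dependency
updates, the death/division bookkeeping, and rate-convention mistakes (a
mean-time/half-life swap shifts a decay curve by ln 2 and fails the
oracle). It does not emulate features of real ICD data — measurement
noise, unmodelled cell types, non-exponential event times, spatial
structure — so passing benchmarks certifies the simulator, not the
biological fidelity of any particular model built on it.
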