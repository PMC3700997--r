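---
title: "Event-driven co-simulation of electrical and biochemical spine signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven co-simulation of electrical and biochemical spine signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesync)
```

## The problem

Synaptic plasticity in a dendritic spine emerges from two tightly coupled
systems that live on very different timescales: the electrical behavior of
the membrane (milliseconds — channel gating, synaptic conductances, calcium
entry) and the biochemical signaling network in the spine head (seconds to
minutes — calmodulin, CaMKII, calcineurin, DARPP-32, PP1, AMPA-receptor
phosphorylation).  Integrating both in one ODE system wastes the stiff
solver on the quiet stretches; running them separately loses the feedback
loop in which calcium entry drives receptor phosphorylation and the
phosphorylated-receptor count sets the synaptic weight of the next
stimulus.

`spinesync` couples the two as *co-simulated* models under an event-driven
meta-simulator.  Each simulator only has to expose three methods — `step`
to an absolute time, `get` and `set` for named scalar variables (the
`sim_handle` contract).  The kernel advances both independently until the
next stimulation event, then forces them through synchronization windows in
which variables are exchanged at a fixed cadence.

## The synchronization cycle and the model hierarchy

One synchronization cycle has four phases: (1) mapped variables are read
from the slow simulator, transformed, and written into the fast one;
(2) the fast simulator advances by the exchange interval delta;
(3) mapped variables are read back from the fast simulator, transformed,
and written into the slow one; (4) the slow simulator advances by the same
delta.  The ordering is fixed: the slow side is read *first*, so the fast
simulator — the one that receives the external stimulus — always holds
up-to-date slow-side values before it moves.  `synchronize_cycle()`
enforces equal clocks at entry and exit; the kernel owns all time
bookkeeping (simulators are told absolute target times), so clock drift
between the two sides cannot accumulate.

After each event the kernel keeps the pair synchronized for
`window_length` ms (default 10), exchanging every `delta_exchange` ms
(default 1).  The defaults are configurable; they are the worked-example
values of the synchronization scheme this package implements.  Three
strategies share this machinery:

* `run_event_driven()` — events known in advance, sorted in a queue;
  every event is delivered exactly once at its exact time.  Events that
  land inside a still-open window extend the window rather than nest; this
  preserves a single timeline and keeps the cycle cadence intact.
* `run_fixed_step()` — the classical while-loop baseline that synchronizes
  at every multiple of `dt_sync`.  An event is delivered only if its time
  coincides with a grid point (absolute tolerance 1e-9 ms, so float
  comparison can never drop an on-grid event); all others are recorded as
  missed.  On a fixture of 240 events spaced 50 ms apart this misses 120
  events (50%) at `dt_sync = 100` ms and none at 10 ms, while the
  event-driven strategy never misses any.
* `run_on_demand()` — for events that emerge during the run: the fast
  simulator is advanced first in scan steps and may report events from its
  last step, each of which triggers the same forced window.  Only the fast
  simulator may emit events.

Wall-clock timings are recorded in every log for information but never
asserted anywhere: they are hardware facts, not model facts.

## The fast simulator: a reduced spiny-neuron electrical model

The electrical model is a compartmental cable: a soma, a reduced
symmetric dendritic tree (per primary dendrite one proximal, one medial
and two distal sections; the full 28-branch arborization can be built with
`tree = "full"`), and one explicit three-section spine per placed spine —
neck, head and PSD cylinders with the reference dimensions (PSD
0.5 x 0.05 um, head 1.175 x 1.0 um, neck 0.1 x 1.5 um, surfaces 0.471,
5.86 and 0.487 um^2 with end caps).  The desk-scale default of one branch
and a handful of spines keeps the double-train experiment far below a
minute of wall time; the reduction is justified by the single-branch
design of the neighbor-spine experiments this class of model is used for.

Channels follow the Hodgkin–Huxley / Boltzmann formalism: steady states
`1/(1+exp(-(V-Vh)/k))` with per-gate time constants, either fixed or
supplied as piecewise-linear voltage lookup tables.  A subset of channels
(slow and fast A-type potassium, N-type and high-threshold L-type
calcium) uses a partial-inactivation coefficient `a`, with effective
inactivation `a*h + (1-a)`; at `a = 1` this is exactly the plain
Hodgkin–Huxley current, and `a < 1` shallows the inactivation depth.
Small- and large-conductance calcium-activated potassium channels are
gated by a Hill function of the local shell calcium instead of voltage.

The published table of gating parameters for this cell type is not
reproduced verbatim here: the package ships its own default channel
library (`default_channel_set()`) with densities and Boltzmann parameters
in the ranges reported for striatal projection neurons, and every number
is configuration, not code.  Channel placement follows the spine
construction rules — both L-type channels in the PSD; Q-, R-, N-type and
SK in the head; the inward rectifier in head and neck — and
`audit_channel_placement()` verifies them on any built model.

Numerics: backward-Euler voltage update solved exactly on the compartment
tree per step (Hines elimination), exponential gate relaxation (exact for
frozen rates over one step), explicit thin-shell calcium update, internal
step 0.025 ms (halving it moves the spine-head peak depolarization by
less than 1%, which the test suite checks).  The integrator aborts with a
diagnostic if any |V| exceeds 200 mV.  Units are mV, ms, um, mM, nS
internally, with conversions centralized.

Calcium enters a 0.1-um shell under each compartment membrane from the
calcium-carrying currents, is extruded by a Michaelis–Menten pump, and
relaxes diffusively with a 43 ms time constant toward the resting
concentration.  The PSD is an internal section of the head, so its calcium
current is routed into the head's shell.  Synaptic (NMDA, and marginally
AMPA) calcium is added as a configurable *effective* fraction of the
synaptic current (defaults 3e-3 and 3e-4).  These fractions are an order
of magnitude below the ionic calcium fractions of the real receptors
because the shell carries no explicit endogenous buffer; the buffering
capacity is folded into the fraction so that single-event spine-head
transients land in the observed micromolar range.

Synapses are co-localized AMPA/NMDA double-exponential conductances on the
PSD (defaults: AMPA 0.5/3 ms, NMDA 2/100 ms, peaks 0.5 and 0.3 nS), each
event normalized so its peak equals `weight * gpeak`.  The published
source does not print the synaptic kinetic constants; these defaults are
standard values for the receptor families and are configurable.  The NMDA
magnesium-block nonlinearity is deliberately not modeled — the upstream
description the model follows does not include it — so NMDA conductance is
ohmic in voltage.  The synaptic `weight` multiplies the AMPA peak
conductance and is the variable the biochemical side controls.

## The slow simulator: the spine signaling network

`build_network()` assembles a deterministic mass-action/Michaelis–Menten
network (M and s internally; the coupling layer owns all unit
conversions):

* **Allosteric calmodulin.**  Two conformations, tense (T, low affinity)
  and relaxed (R, high affinity), each binding four calcium ions
  sequentially with a shared diffusion-limited on-rate and per-step
  off-rates.  Conformational transitions are available at every occupancy
  (`cam_switching = "all_levels"`); the concerted limit with transitions
  only for empty and fully loaded calmodulin is one flag away
  (`"endpoints"`).  The transition rates are *derived* from the allosteric
  constant L0 and the off-rate ratios so the thermodynamic cycle closes by
  construction (detailed balance): `L_i = L0 * prod(koff_r/koff_t)[1..i]`,
  `k_RT = k_conf * sqrt(L_i)`, `k_TR = k_conf / sqrt(L_i)`.
* **Two calcium sensors.**  Calcineurin binds the three-calcium relaxed
  conformation — abundant already at a few hundred nanomolar calcium —
  while CaMKII requires fully loaded calmodulin, making it the
  high-calcium sensor.  This affinity/occupancy split is what routes low
  sustained calcium to the phosphatase branch and strong transients to
  the kinase branch.
* **Kinase branch.**  The CaMKII–calmodulin complex autophosphorylates at
  Thr286 (a single first-order constant; holoenzyme subunit cooperativity
  is deliberately not modeled), which traps the complex until PP1
  dephosphorylates it through an explicit enzyme–substrate scheme.  The
  complex (phosphorylated or not) phosphorylates AMPA receptors at Ser831
  (Michaelis–Menten).
* **Phosphatase branch.**  PKA phosphorylates DARPP-32 at Thr34;
  phospho-DARPP-32 binds and inhibits PP1; the calcineurin–calmodulin
  complex dephosphorylates phospho-DARPP-32, releasing PP1, which
  dephosphorylates both phospho-CaMKII and phospho-AMPA receptors.
* **Calcium housekeeping.**  A Michaelis–Menten pump, a constant leak
  balancing it at the ~100 nM resting point, and the zeroth-order influx
  process the coupling layer drives.  A negative influx (mirroring a
  declining electrical calcium) fades out smoothly as free calcium
  approaches zero — a hard floor would be a discontinuity that stalls the
  stiff solver.

The published parameter tables for this network are not reproduced in the
material this package was built from (the extraction retains the table
*structure* but not the numeric cells), so the defaults in
`default_biochem_params()` / `default_initial_concentrations()` are the
package's own literature-informed reconstruction of the same model
families, balanced once so that the textbook behavior holds and then
frozen:

* at rest, PKA keeps DARPP-32 mostly phosphorylated, PP1 is largely
  sequestered (~16 nM free of 2 uM), and the AMPA-receptor phospho-cycle
  sits at an interior equilibrium (~19% phosphorylated) maintained by
  opposing kinase and phosphatase fluxes;
* sustained calcium around 0.2–0.3 uM engages calcineurin, collapses
  phospho-DARPP-32, frees PP1 several-fold and drives net
  *de*phosphorylation (the depression regime, developing over minutes —
  the phosphatase pathway acts late, in keeping with the delay introduced
  by the calcineurin/DARPP-32 relay);
* calcium transients above ~1 uM load calmodulin fully, activate CaMKII,
  and drive net phosphorylation within seconds (the potentiation regime).

Concentrations are the working currency; molecule counts are derived at
reporting time over the spine-head cylinder volume (1.084 fL), never
rounded internally.  Five conserved moieties — calmodulin, CaMKII,
DARPP-32, PP1, AMPA receptor — are audited by `moiety_totals()` and must
stay constant to 1e-6 relative over any protocol.  Integration uses a
stiff-capable adaptive solver (lsoda) that transparently resumes if a
stiff stretch exhausts its step budget.  `equilibrate()` relaxes the
network until the largest relative derivative falls below 1e-8 per second;
the slowest basal mode (turnover of the nearly exhausted free DARPP-32
pool, timescale ~1e5 s) is integrated out honestly — the solver crosses
the quiet approach in a handful of large steps, so full equilibration
costs about a second of wall time.

## The coupling

Two quantities cross the boundary, once per cycle
(`hybrid_coupling()`):

* **Calcium, fast to slow.**  The electrical shell concentration is not
  copied into the biochemical model — free calcium there is instantly
  buffered by calmodulin, so copying would produce a sawtooth artifact.
  Instead the *discrete derivative* of the electrical calcium over the
  exchange interval becomes the rate of a zeroth-order influx process
  (`flux_constant()`; mM/ms and M/s coincide numerically).  The sign is
  preserved, so decline is mirrored as decline.  Sampling uses the
  interval endpoints (the fixed-cadence scheme); when a window closes the
  influx constant is zeroed, because a derivative estimated inside the
  window must not keep extrapolating while the simulators run free.
  With this scheme the *total* (free plus calmodulin-bound) biochemical
  calcium reproduces the electrical waveform over a stimulation window
  (Pearson r > 0.9 in the test suite).
* **Weight, slow to fast.**  The phosphorylated-receptor concentration is
  converted to a count over the head volume and normalized by its stored
  equilibrium count (`compute_weight()`): weight 1 at rest, above 1
  potentiated, below 1 depressed.  The exact normalization of the
  published rule is not printed; the ratio-to-equilibrium form is chosen
  because it expresses the weight as the relative change between resting
  and excited conditions, and the alternative affine form differs only by
  a reparameterization.  The weight is also refreshed immediately before
  each event is delivered, so a stimulus always uses the up-to-date
  weight, and it multiplies the AMPA conductance only at event insertion —
  already-decaying conductance transients are never rescaled.

Between windows the two simulators evolve independently and no mapped
variable changes — the transform log in every `sync_log` lets tests assert
this directly.

## Experiments and what the defaults emulate

`run_experiment()` wires everything together: electrical model with all
spines instantiated, one equilibrated biochemical instance per
*stimulated* spine only (biochemical spines are created on demand — an
unstimulated spine stays purely electrical), trains merged into one event
queue, and the chosen synchronization strategy.  The desk-scale default
protocol is the single-spine double train: 8 Hz, 20 inputs per train,
trains starting at 2000 and 15000 ms, 18 s of simulated time — a
down-scaled version of the published 50-input protocol (durations follow
the `n_inputs / frequency` convention, e.g. 6.25 s at 8 Hz for 50
inputs).  With the biochemistry enabled the first train potentiates the
synapse; the phosphorylated-receptor count keeps rising for seconds after
the train ends (the slow timescale *is* the memory), and the second train
meets a stronger synapse — its peak spine-head depolarization exceeds the
first train's by over 10 mV under the defaults.  With the biochemistry
disabled the difference vanishes.  Electrical traces are recorded at 1 ms,
biochemical at 10 ms (both configurable).

The whole pipeline is deterministic: identical configurations reproduce
archives bit-for-bit, and the config snapshot written into every archive
is sufficient to rerun the experiment (`read_archive_config()`).  The
`seed` field names a run; no randomness is consumed by the deterministic
pipeline (only the optional noisy synthetic density profile uses it,
explicitly).

What passing these protocol tests does *not* show: the synthetic defaults
emulate the published study conditions, not a particular neuron; the
channel and kinetic constants are reconstructions, so quantitative traces
(absolute depolarizations, absolute receptor counts) are not comparable to
any specific experiment — only the structure of the behavior (event
bookkeeping, conservation, regime switching, the order and sign of the
plasticity effects) is.

## Spine distribution

The morphology module reproduces the budget arithmetic that converts a
folded ("spine-corrected") membrane surface back into explicit spines:
corrected minus original surface (14973 − 5278 = 9695 um^2), divided by
the per-spine exposed surface (6.35 um^2: head + neck with caps, PSD
excluded), floored to 1526, symmetrized to the largest multiple of the
four primary dendrites (1524, i.e. 381 per branch).  The folding
transform itself (`segev_fold()`: length x F^(2/3), diameter x F^(1/3))
scales lateral area exactly by F.  Flooring (not rounding) is used because
it reproduces the published 1526.  The reference density data place five
spurious spines per branch over the soma and proximal dendrites
(digitization noise); removing them gives the final 376 per branch, 1504
total.  (The published text and figure caption disagree — 376/1504 versus
371 per branch — and the text value is taken as authoritative.)
`spine_budget()` keeps the noise removal as an explicit parameter, while
`distribute_spines()` implements the generalized form: a proximal
distance cutoff.

Density profiles are fitted with an order-17 polynomial in the orthogonal
basis (a raw power basis is numerically singular at that order), clamped
at zero with clamp counts reported.  The digitized density data behind the
published distribution are not available, so
`synthetic_density_profile()` generates a fixture with the same
qualitative shape — zero over soma and proximal dendrites, peak near
50 um, slow distal decay — and user profiles are accepted as two-column
tables.  Placement integrates the fitted density along a branch path,
takes the per-dendrite share (one quarter for a four-dendrite tree), and
emits a spine each time the running integral crosses a multiple of the
per-spine area: deterministic, never over-allocating, and exactly the
closed-form count for a uniform density.

## Design choices worth recording

* **Window extension, not nesting.**  An event arriving inside an open
  synchronization window is delivered at its exact time and extends the
  window; nested windows would double-exchange the same interval.
* **Truncated cycles.**  An event falling between exchange points splits
  the cycle so delivery happens exactly on time; cadence resumes after.
* **Zeroed influx at window close** — see the coupling section; without
  it a stale positive derivative integrates into millimolar phantom
  calcium between windows.
* **Effective synaptic calcium fractions** stand in for explicit
  endogenous buffering (see the electrical section).
* **Calcineurin reads partially loaded calmodulin.**  With both sensors
  reading only the fully loaded state, no parameter choice yields a
  depression regime: kinase trapping (fourth power of calcium) outruns
  any phosphatase release at every calcium level.  The three-calcium
  sensor is the standard resolution and is what the two-pathway switch
  logic requires.
* **Problem sizes.**  Default experiments use one dendritic branch and
  up to ~20 spines over <= 20 s simulated; these sizes keep the full
  suite and the example protocols in the minutes range on a laptop while
  preserving every qualitative result.  The full symmetric tree and the
  1504-spine build remain available through configuration.

## Limitations

Calcium diffusion between spines is not modeled (neighbor effects are
purely electrical, via voltage-gated channels); the biochemical engine is
deterministic — no stochastic reaction events, no spatial gradients within
the spine; dopamine-side signaling upstream of PKA is a fixed input;
rollback-style synchronization is out of scope (the model hierarchy
requires strictly sequential advancement); and the wall-clock comparisons
between strategies are reported but never asserted.
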