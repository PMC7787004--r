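---
title: "Models and methods behind burstnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind burstnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

burstnet simulates rhythm generation in developing spinal interneuron
networks — the kind of circuit exemplified by Shox2 interneurons in the
neonatal rodent cord, where neighbouring cells are coupled bidirectionally
by gap junctions with high incidence (probability ~0.3) and sparsely by
unidirectional excitatory chemical synapses (~0.1). This vignette explains
the model, the measurement conventions, the numerical choices and the known
limitations; the README shows a worked example.

## The neuron model

Every neuron is a single-compartment Hodgkin–Huxley model with fast sodium,
delayed-rectifier potassium and leak currents:

$$C \dot V = -I_{Na} - I_{NaP} - I_K - I_L - I_{Syn} + I_{Gap}$$

with $I_{Na} = \bar g_{Na} m_{Na}^3 h_{Na}(V - E_{Na})$,
$I_K = \bar g_K m_K^4 (V - E_K)$, $I_L = g_L (V - E_L)$, and, in a subset of
cells, a persistent (slowly inactivating) sodium current
$I_{NaP} = \bar g_{NaP} m_{NaP} h_{NaP} (V - E_{Na})$. Standard constants:
$C = 40$ pF, $\bar g_{Na} = 80$ nS, $\bar g_K = 100$ nS, $g_L = 1$ nS,
$E_{Na} = 55$ mV, $E_K = -80$ mV. Units are mV, ms, nS, pF throughout, so
nS·mV = pA and pA/pF = mV/ms: the membrane equation is dimensionally closed
with no hidden conversion factors. Quantities quoted in seconds (the slow
inactivation ceiling `t_hmax`, simulation durations in config files with an
`_s` suffix) are converted to ms at construction/load time.

Gating variables follow first-order relaxation
$\tau_x(V)\dot x = x_\infty(V) - x$ with Boltzmann steady states and
bell-shaped (reciprocal-cosh) time constants peaking at the half-voltage
(`gate_inf()`, `gate_tau()`). Both sodium activation gates are
instantaneous: they are evaluated algebraically as $m_\infty(V)$ at every
derivative evaluation rather than integrated, which is both exact and
stiffer-proof than integrating a near-zero time constant. The
delayed-rectifier has no inactivation.

$I_{NaP}$ is what makes a neuron a *conditional burster*. Its activation is
fast (half-voltage −52 mV) but its inactivation gate $h_{NaP}$ recovers and
decays on a seconds time scale (ceiling `t_hmax`, default 9 s): at suitable
leak reversal potentials the cell alternately bursts (inactivating
$h_{NaP}$) and recovers in silence. The leak reversal `e_l` positions the
cell in one of three regimes — silent, bursting, tonic spiking — and is the
main excitability dial in all experiments: an isolated burster model leaves
silence around −72 mV and switches to tonic spiking around −65 mV, while a
neuron without $I_{NaP}$ starts to spike tonically near −59.5 mV.

## Coupling

Gap junctions are ohmic and bidirectional:
`gap_currents()` returns $\sum_i g_{Gap,ij}(V_i - V_j)$, which the membrane
equation receives with *depolarizing* sign, so coupling always pulls a
neuron's potential toward its neighbours' (membrane-potential
equilibration). Written with the opposite sign the same expression would
make a depolarized neighbour hyperpolarize its partner, contradicting every
observed effect of electrical coupling; we therefore treat the sign as
fixed by the physics. Pairwise terms are antisymmetric, so gap currents sum
to zero over the network at every instant — a conservation law the tests
assert.

Chemical synapses are AMPA-like conductances with reversal 0 mV and unit
conductance 1 nS scaled by a weight $w_{Syn,ij}$:
$I_{Syn,j} = g_{Syn}(\sum_i w_{Syn,ij}\, s_i)(V_j - E_{Syn})$. Each
presynaptic neuron carries one output gate $s \in [0,1]$ with first-order
kinetics $\dot s = \alpha_s s_\infty(V)(1-s) - s/\tau_s$,
$\alpha_s = 1\,\mathrm{ms^{-1}}$, $\tau_s = 15$ ms and a Boltzmann
$s_\infty$ with half-activation −20 mV and slope 2 mV. The gate is
integrated for every neuron, including those with no outgoing synapse: the
uniform state layout costs nothing and keeps the integrator branch-free.

With these constants the gate charges to roughly 0.8 during each
presynaptic spike (spikes spend ~1.8 ms above −20 mV), which makes the
synapse a strong entrainer: a bursting source locks a silent target 1:1
already at $w_{Syn} = 0.5$–1, and in populations recurrent excitation
drives the network to sustained tonic firing at aggregate couplings
$W \gtrsim 1$. Weaker effective gates (for example a higher half-activation
voltage, which opens the gate only near the spike peak) would shift all
chemical-coupling phenomena to several-fold larger $w_{Syn}$; we keep the
stated constants and note that all chemical-coupling results should be read
on this package's own $W$ scale.

## Populations

`population_spec()` describes the standard heterogeneous population:
$N = 100$ neurons, $N_{NaP} = 40$ conditional bursters, leak reversals
Normal(−74, 14.8) mV in the $I_{NaP}$ subpopulation and Normal(−70, 14) mV
in the rest, $g_L \sim$ Normal(1, 0.2) nS, $\bar g_{NaP} \sim$
Normal(4, 0.8) nS — the ± values are interpreted as one standard
deviation, consistent with their uniform 20%-of-mean pattern. Draws are
truncated at ±3 SD and conductances floored at 0, because the stated SDs
otherwise occasionally produce non-physical parameters (negative
conductances, leak reversals above 0 mV); the truncation leaves 99.7% of
the distribution untouched. Connectivity is Bernoulli per pair:
probability 0.3 for gap junctions (per unordered pair, bidirectional) and
0.1 for chemical synapses (per ordered pair; reciprocal pairs may arise by
chance — "unidirectional" describes the single synapse, not a topological
exclusion). Aggregate couplings $G = N p_{Gap} g_{Gap}$ and
$W = N p_{Syn} w_{Syn}$ summarize the expected total electrical and
chemical input per neuron.

Initial conditions are Normal($E_L$, 5 mV) for the membrane potential,
gates at steady state for the drawn potential, synaptic gates at 0; no
distribution is canonical here, and the settling period discarded before
any analysis (default 20 s for populations, within the conventional
10–40 s range; 20 s for two-cell runs) absorbs the residual dependence.
One integer seed fixes parameters, connectivity and initial state, making
every run exactly reproducible.

## Integration

The coupled system is advanced by a fixed-step second-order Runge–Kutta
(midpoint) scheme, `dt` = 0.05 ms by default. No step size is canonical for
this model family; 0.05 ms is standard for Hodgkin–Huxley spikes, and the
suite verifies that halving it changes intrinsic burst frequencies by less
than 1%. An adaptive high-accuracy integrator (deSolve's `lsoda` on an
independent transcription of the equations) serves as the oracle in tests —
single-neuron trajectories, spike shapes and two-cell entrainment all
match — but never in the production path.

Two numerical guards keep the explicit scheme honest without altering the
dynamics at working step sizes: gate values are clamped to $[0,1]$ when
read and after each full step (floating-point overshoot absorbs there), and
gate time constants are floored at `dt`. The floor matters only in deep
voltage saturation, where $\tau \propto 1/\cosh$ falls to microseconds
while the gate is pinned at its steady state; without it, the midpoint
stage can push a gate far outside $[0,1]$ and the fourth-power potassium
activation amplifies the excursion into a blow-up. Non-finite states abort
the run with the neuron index and time.

Inside the compiled core the Boltzmann/cosh nonlinearities are evaluated
from piecewise-linear lookup tables on a 0.01 mV grid over [−120, 60] mV —
the standard table trick of Hodgkin–Huxley network simulators.
Interpolation error is ~1e−7 on the gate values; the R-level functions
evaluate the exact expressions, and tests pin both against an independent
transcription. Spikes are recorded online as upward crossings of −20 mV
with a 2 ms refractory guard — unambiguous for these spikes, which
overshoot well past the threshold — so spike trains are exact at the
integration resolution even when voltage traces are subsampled (default
1 ms) or not recorded at all.

## Measurement conventions

**Single-neuron bursts** (`spike_bursts()`). Spikes are grouped into bursts
wherever the inter-spike interval stays below max(300 ms, 3 × median ISI),
which cleanly separates the ~10–100 ms intra-burst intervals from
multi-second pauses across the whole 0.05–0.45 Hz range and leaves a
regular tonic train as a single group. Conditional bursters near threshold
emit a short rebound miniburst (2–3 spikes) beside each main burst,
separated by a sub-second pause that belongs to the same slow
$h_{NaP}$ cycle; bursts with at most 25% of the upper-quartile
spikes-per-burst are
therefore merged into the neighbouring burst across the shorter gap. The
burst onset is the first spike of a burst, the period the onset-to-onset
difference, and the frequency its reciprocal — so frequency × mean period
is exactly 1. Fewer than two bursts leave the frequency undefined.

**Regimes.** A neuron is *silent* with fewer than 3 spikes in the analysis
window, *bursting* with at least two detected bursts, *tonic* otherwise. A
"resting potential" is reported even for active cells, as the only settled
spike-free measure available: mean potential over the last 5 s when silent,
otherwise the mean of the local minima between bursts (bursting) or between
consecutive spikes (tonic).

**Populational activity.** The population rate is the spike histogram in
100 ms bins scaled to spikes per neuron per second. Burst detection is
two-pass: provisional peaks (local maxima of the lightly smoothed rate, at
least 0.5 s apart, reaching half the maximum) define the average burst
amplitude; onsets are then upward crossings of a threshold at 30% of that
amplitude, read off the 3-bin smoothed rate so Poisson binning noise cannot
trigger spurious onsets. A detected burst must itself reach half the
average amplitude (precursor bumps on a cycle's rising phase are
discarded), and onsets closer than a third of the median cycle are thinned.
This deterministic rule replaces the manual re-thresholding a human analyst
would apply to less stable simulations. Each run is assigned exactly one of
four labels: *none* (peak rate below 1 spike/neuron/s), *tonic* (mean rate
at least 10 with no dip below the onset threshold), *low/unstable* (burst
amplitude below 10 spikes/neuron/s, period SD at least 50% of the mean, or
too few bursts to certify stability), else *stable bursting*.

**Synchrony** is summarized as the mean pairwise Pearson correlation of
100 ms binned spike counts over a chosen subset (typically the $I_{NaP}$
subpopulation); zero-variance neurons are excluded pairwise.

**Burst ratios** between two onset series (e.g. a weak chemical synapse
entraining a target every other cycle) are the burst counts over the
common window snapped to the nearest small rational (denominator ≤ 4)
when within 15%, with 1:1 additionally requiring equal counts.

## Experiment drivers and problem sizes

`run_two_cell()` integrates a pair for 20 s settling plus a 100 s analysis
window by default (extended to 160 s where very slow rhythms need more
cycles) — each run takes a few seconds. `reproduce_table()` recomputes
both published two-cell benchmark tables (13 neuron pairs × 4 coupling
strengths) and verdicts each cell at ±20% on frequencies and ±1.5 mV on
voltages; the frequency tolerance is deliberately wide because the
two-cell `t_hmax` is not independently specified (we use the populational
9 s) and burst-onset conventions are implementation-defined.
`run_population()` uses 20 s settling plus 60 s of analysis; sweeps
(`sweep_gw()`, `sweep_gnap()`) reuse one randomization across grid cells
so cells differ only in coupling strength, mirroring how connection
strengths are varied after the connectivity draw. The gap-junction-block
comparison (`carbenoxolone_compare()`) models carbenoxolone as a 50%
reduction of every gap conductance and reports paired frequency and
baseline-normalized amplitude over five randomizations (60 s each); its
baseline is the canonical stable-bursting condition $g_{Gap} = 0.066$ nS.

These sizes keep a full two-table benchmark under ten minutes and each
population condition in tens of seconds on one core, while providing 10–20
analyzable cycles per run for 0.1–0.4 Hz rhythms.

## What the synthetic fixtures do and do not show

Test fixtures are generated in code: jittered spike trains with known burst
onsets, sharp-rising populational bursts with Poisson-scale additive noise,
Bernoulli connectivity draws with binomial count statistics. They verify
that the measurement layer recovers ground truth that is *constructed* to
have the assumed shape (compact bursts, quiescent gaps, roughly periodic
cycles). They do not probe pathologies real recordings have — drifting
baselines, slow amplitude trends, electrode artifacts — and the package
deliberately excludes the wet-lab processing chain (rectification,
smoothing of ventral-root signals): passing tests certify the model and its
measurement conventions, not readiness for experimental data.

## Known limitations

- Only $I_{Na}$, $I_K$, $I_L$, $I_{NaP}$ are modelled; calcium and
  calcium-dependent currents, h-current and the Na/K pump — all plausibly
  relevant to developing spinal rhythmogenesis — are out of scope, as are
  inhibitory interneurons and left–right coordination.
- The chemical-synapse gate constants make the synapse a stronger
  entrainer than the published two-cell benchmark table implies (see
  *Coupling*); chemical-coupling results are internally consistent but sit
  on a compressed $W$ scale, and with the standard populations no
  chemical-only stable-bursting window exists between the irregular and
  tonic regimes.
- Populational frequency trends under coupling changes depend on the drawn
  excitability distribution: with the stated leak-reversal distributions
  the bursting cluster is net-loaded by the hyperpolarized majority, so
  stronger electrical coupling slows the rhythm once synchronization is
  complete rather than speeding it up.
- Fixed-step RK2 is the production integrator by design; stiff extremes
  are guarded (gate clamping, time-constant floor) rather than adaptively
  resolved.
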