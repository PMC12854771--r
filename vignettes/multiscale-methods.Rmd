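---
title: "From channel gating to neuronal spikes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From channel gating to neuronal spikes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionspike)
```

ionspike links two scales of neuronal biophysics. In one direction,
single-channel conductances of AMPA-receptor variants (measured by counting
ion permeation events through the pore) are converted into synaptic scaling
factors that drive a compartmental neuron model under Poisson synaptic
bombardment. In the other, a coarse-grained lattice Monte Carlo model of
voltage-gated Na⁺/K⁺ channels embedded in a binary lipid membrane is coupled
bidirectionally to a membrane-potential solver: the patch current shapes the
voltage, and the voltage feeds back into the gating energetics. This
vignette describes the models, the parameter choices that were genuinely
open, and what the shipped defaults do and do not demonstrate.

## The lattice membrane model

A patch of neuronal membrane is an `L × L` periodic square lattice. Every
site holds exactly one occupant: a saturated lipid, an unsaturated lipid, or
a channel. Each channel carries four voltage sensors facing its four lattice
neighbours; a channel conducts if and only if all four sensors are
activated. The Hamiltonian has a *gating* term and an *interaction* term:

$$H = \sum_{\text{channels}} \sum_{s=1}^{4} \sigma_s\,
      (\varepsilon_g - q\,V_m F_v)
    + \sum_{\langle ij \rangle} J(o_i, o_j),$$

with $\sigma_s \in \{0,1\}$ the sensor state, $q$ the gating charge per
sensor (default 1.5 $e_0$), $F_v$ the conversion from $e_0\!\cdot\!$mV to the
energy unit $k_B T_{\mathrm{ref}}$ ($T_{\mathrm{ref}} = 303.15$ K), and $J$
a nearest-neighbour coupling: lipid–lipid via a symmetric 2×2 matrix,
channel–lipid via a table indexed by the state of the sensor *facing* that
neighbour and the lipid species. Channel–channel contacts carry no bond
energy; allosteric linkage between sensors enters only through the
all-four-activated conduction rule (an explicit sensor–sensor constant is
exposed and defaults to 0). In the zero-coupling limit each sensor is an
isolated two-state system, so its stationary activation is the sigmoid
$p(V_m) = 1/(1+e^{\beta(\varepsilon_g - qV_mF_v)})$ with midpoint
$V_{1/2} = \varepsilon_g/(qF_v)$ — the exact limit the test suite checks
against, together with an exact 16-state Boltzmann enumeration of a single
channel on a 3×3 lattice.

Dynamics are Metropolis Monte Carlo with four move types (default mix
0.5/0.3/0.15/0.05): sensor flips, Kawasaki lipid swaps (composition is
conserved — the study design holds stoichiometry fixed and moves through the
phase diagram with temperature alone), channel translation into a
neighbouring lipid site, and ±90° channel rotation, which permutes the
sensor→neighbour map. Proposals that would break an invariant (translating
onto a channel) count as attempted and rejected, keeping the proposal
distribution well defined. Energies are tracked incrementally and checked
against full recomputation to 10⁻⁸ relative.

### Why the lipid coupling is ±0.45

For a two-dimensional binary mixture with like-pair attraction $-J$ and
unlike-pair repulsion $+J$, the demixing critical point sits at
$\beta K_c \approx 0.4407$ with $K = J_{\mathrm{unlike}} -
J_{\mathrm{like}} \over 2$ (Onsager). With energies in $k_B T_{\mathrm{ref}}$
units, $|J| = 0.35$ puts criticality near 241 K — far below any
physiological temperature, so a 20–40 °C scan would probe essentially
nothing. $|J| = 0.45$ places the critical temperature at ≈ 309.6 K (36 °C):
the same nominal mixture is a single mixed fluid at 40 °C and sits at or
below the demixing boundary at 30 and 20 °C, which is precisely the
temperature-scan design the membrane study calls for.

## The cable solver

Morphologies are trees of frustum segments with `soma`/`dendrite`/`axon`
labels, read and written as standard 7-column SWC (each edge is treated as a
cylinder of its child point's radius, which makes the writer/reader a
lossless round trip for the package's generators and sidesteps the radius
ambiguity at region boundaries). `discretize()` splits segments into
compartments no longer than `max_len` µm (somata stay single compartments),
conserving membrane area exactly; axial conductances come from the exact
frustum resistance integral $R = 4 r_a L / (\pi d_0 d_1)$ combined as half
resistances between compartment midpoints.

The membrane carries leak plus classic squid-type Hodgkin–Huxley Na/K
mechanisms on the modern voltage scale (rest ≈ −65 mV; $E_{Na}=+50$,
$E_K=-77$, $E_{leak}=-54.3$ mV; default densities 0.12/0.036 S cm⁻² on soma
and axon, passive dendrites), with rates scaled by
$q_{10}^{(T-T_{base})/10}$, $q_{10}=3$, $T_{base}=6.3$ °C. Integration is
backward Euler (default dt 0.025 ms) with the linearized system solved
exactly by tree-ordered Hines elimination — unconditionally stable through
stiff spikes — and exponential integration of the gate ODEs. The analytic
test battery covers RC charging (< 0.1 mV), steady-state cable attenuation
against the $\cosh((L-x)/\lambda)/\cosh(L/\lambda)$ profile (< 1%),
first-order error decay in dt, interior charge balance at steady state, and
spike-shape plausibility (peak > 0 mV, width at −20 mV under 5 ms) on the
default soma.

Spike detection is an upward threshold crossing with a refractory window
(defaults −20 mV and 2 ms). The biological initiation threshold in
pyramidal cells sits around −53..−45 mV, but a counting criterion that low
double-counts noisy shoulders; both settings are configurable.

## The synaptic pipeline

Variant scaling factors are conductance ratios against the pore-edited
baseline receptor, $G = g_{MD}/g_{\mathrm{baseline}}$, reported at one
decimal (half-up). A coarser integer rounding used for simulation sweeps
rounds the one-decimal value to the nearest integer with ties down — the
published table prints 3.5 → (3) — and maps 28.0 → 30 by that table's own
convention. The conductance table ships in
`inst/extdata/variants.tsv`; the wild-type row (10.2 ± 4.6 pS) is the
tabulated average (the running text of the source study quotes 9.6 pS; the
table is treated as canonical here).

Synapses are peak-normalized double exponentials: a single event reaches
exactly `weight × G` µS at
$t_p = \tau_r\tau_d/(\tau_d-\tau_r)\,\ln(\tau_d/\tau_r)$; events superpose
linearly. The kinetics default to $\tau_r = 0.2$ ms, $\tau_d = 1.7$ ms —
typical fast AMPA-receptor values, chosen because the study's own kinetic
constants are not published; both are configurable. The literature weight
of 1.5 µS is kept as a config default but is model-scale, far above
single-synapse physiology; quantitative spike thresholds therefore come
from `calibrate_baseline_weight()`, a bisection for the largest weight at
which the baseline receptor stays silent under uncorrelated 10 Hz Poisson
input while a 30× gain-of-function probe fires. Placement is either
*localized* (ten synapses inside a 50 µm sphere around a random dendritic
compartment, emulating clustered input) or *distributed* (uniform over the
dendritic tree); "segments" are the discretized dendritic compartments,
with distances between 3D midpoints.

On the shipped random dendritic tree, the calibrated experiments show the
qualitative gain-of-function phenotype: the baseline is silent, the spike
count is non-decreasing in $G$ over {1, 3, 6, 30}, and correlated input
reaches spiking at a smaller $G$ than uncorrelated input. Note a subtlety:
at a weight calibrated against the *uncorrelated* baseline, perfectly
synchronized input is capped by the event count of its single shared train,
so for large $G$ the uncorrelated ensemble can emit *more* spikes than the
correlated one. The robust, mechanism-level statement — which the tests
assert — is about thresholds: synchronized input needs less conductance
scaling to fire the cell. The specific published thresholds (~10× baseline
for distributed, ~30× for localized input) belong to a particular layer-5b
pyramidal reconstruction and are not asserted on the synthetic morphology.

## The bidirectional coupling

The coupled system alternates windows of `exchange_dt` ms: the patch runs
`sweeps_per_ms × exchange_dt` Monte Carlo sweeps at the current somatic
voltage; the window-mean patch current $I = \sum_X n_{open,X}\gamma_X(V_m -
E_X)$, scaled by `area_scale` and sign-flipped to injection convention, is
injected into the soma as a piecewise-constant current while the solver
advances; the end-of-window somatic voltage becomes the patch's $V_m$.
Exchanging the window *mean* rather than the endpoint halves the
exchange-interval sensitivity; fractional sweep counts are carried across
windows, so refining `exchange_dt` does not change the underlying kinetic
rate (halving it moves the ensemble-median peak by well under 2 mV).
Replicas share the initial configuration and differ only by the seed of the
patch's random stream. Two exact contracts anchor the scheme: a channel-free
patch reproduces the solver-only run bit for bit, and a patch frozen in the
all-open state is equivalent to adding a static conductance.

### The default coupled study and its time mapping

The Monte Carlo model has no intrinsic clock, so mapping sweeps to
milliseconds is a modelling choice. The shipped default is 2 sweeps per ms
with 0.5 ms exchange windows. This puts sensor-gating relaxation on the
millisecond scale of Hodgkin–Huxley kinetics; at much faster mappings the
gating equilibrates within a fraction of a millisecond and the channel
population simply tracks its stationary activation curve, which removes the
kinetic lag between Na⁺ recruitment (midpoint −46 mV) and the
higher-threshold K⁺ population (midpoint −31 mV) that generates
regenerative spikes.

In the coupled study the patch channels *are* the cell's voltage-gated
conductances: the two-compartment cell (10 µm soma, 100 × 1 µm dendrite) is
passive, and a patch of 125 Na⁺ and 290 K⁺ channels (γ = 20 pS, area scale
2, 40% unsaturated lipid) supplies the active currents. The K⁺ excess and
its right-shifted midpoint let sodium win transiently during an upstroke
while potassium dominates the depolarized steady state. An 80 pA somatic
clamp from 50–150 ms — a standard patch-clamp amplitude for eliciting
pyramidal spiking — drives repetitive patch-driven spikes with peaks near
−10 mV; the scan's spike counter therefore uses a −30 mV threshold.

Temperature enters the scan through the Monte Carlo energetics only: the
membrane study varies the *patch* temperature, and its effect is mediated by
lipid phase behaviour, not by the neuron's channel kinetics. (The solver's
q10 machinery exists and can be scanned too via `scan_solver_temperature`,
but squid-type HH rates heat-block near 30 °C, which would confound the
membrane effect with an unrelated solver artifact.)

What the default scan shows: cooling from 40 to 20 °C prolongs the
post-stimulus repolarization monotonically while leaving the median spike
peak essentially unchanged (shifts of ~0.1 mV). At 40 °C, above the lipid
demixing point, the membrane returns to rest within ~100–150 ms of clamp
offset. At 20 °C the activated channels sit in unsaturated-lipid wetting
shells that stabilize the open state; the open Na⁺ population then holds the
membrane depolarized, and in most replicas it does not repolarize within the
600 ms window at all — the hysteresis/long-term-memory phenomenology this
model family is known for. `temperature_scan()` therefore reports two
summaries: a per-spike median over uncensored repolarizations (which at low
temperature only sees the replicas that happened to escape, a selection
bias) and a censoring-aware *post-stimulus* median, in which a replica that
never returns to within 5 mV of its pre-stimulus baseline contributes the
remaining trace length as a right-censored lower bound. The directional
claim — colder membranes repolarize more slowly — is asserted on the floor
medians; the magnitude is not asserted, since it depends on unpublished
parameters of the original membrane model.

## Synthetic data generators

`make_ball_and_stick()` (spherical-equivalent soma cylinder; the default
soma height is 20 µm) and `make_random_tree()` (binary tree, always fully
branched for the first three levels so ten-synapse placement is feasible,
then Bernoulli branching with tapering diameters) stand in for the
reconstructed pyramidal morphology, which is not redistributable here.
`make_drift_trajectory()` produces biased random walks through a pore slab
together with the exact crossing events implied during generation, so the
permeation counter can be validated against known truth; drift is in Å/ns
and diffusion in Å²/ns, scales on which nanosecond-length synthetic runs
actually cross. What passing these tests shows is that the counting and
conversion machinery is exact; it does not reproduce the published
per-variant conductances, which would require the microsecond all-atom
trajectories themselves.

Permeation counting semantics, pinned explicitly because toolkits differ: a
passage must be *observed* inside the slab (a single-frame jump across the
whole slab does not count); a lateral excursion beyond the optional gate
radius while inside aborts the passage; z is unwrapped across periodic
jumps larger than half the box height before classification; current uses
net (up − down) crossings, with gross counts reported alongside. Block
standard errors assign events to time blocks by exit time from one counting
pass, so passages spanning a block boundary are kept.

## Numerical and degenerate-input conventions

Internal units are mV, ms, nA, µS, nF (1 µS·mV = 1 nA), with pA at the user
interface; energies in $k_B T_{\mathrm{ref}}$; e = 1.602176634 × 10⁻¹⁹ C
exactly. `run_cable(t_stop = 0)` returns the single initial sample;
conductance at $V_m = 0$ is refused with guidance; an overfull lattice, a
nonpositive conductance ratio, degenerate morphology geometry, and a
placement sphere with too few candidates raise classed errors. Replica
ensembles drop diverging replicas and fail if more than 10% abort. All
generators and simulators are pure functions of (configuration, seed); the
Monte Carlo stream is an explicit PCG32 state carried inside the patch
object, so runs are bit-reproducible across platforms independent of R's
global RNG.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script scales are chosen to be desk-sized:
sigmoid checks on a 10×10 lattice with 12 channels across a 7-point voltage
grid (8 independent replicas for the Monte Carlo standard error); the exact
enumeration check at 10⁶ sweeps on 3×3; bookkeeping invariants over 10⁵
sweeps on 20×20; 100 drift-diffusion ensembles of 10 ions × 300 frames for
the counter equivalence; 1 s synaptic experiments on a ~100-compartment
random tree; and 20-replica coupled ensembles over 600 ms at two to three
temperatures. These finish in minutes while leaving each assertion
statistically meaningful.

## Known limitations

No channel inactivation (the depolarized memory state at low temperature is
partly a consequence); no sphingomyelin/cholesterol lipid species; no
calcium dynamics or synaptic plasticity; single-patch-to-soma coupling
rather than spatially distributed patches; the published absolute traces
and conductances are not reproducible at desk scale and are treated as
directional or structural targets only.
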