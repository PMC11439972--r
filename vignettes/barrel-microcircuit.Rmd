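---
title: "A layered barrel-cortex microcircuit with PV, SOM and VIP interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layered barrel-cortex microcircuit with PV, SOM and VIP interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelsim)
```

## The model

`barrelsim` simulates one mouse C2 barrel column (200 x 300 um footprint)
as a network of 6448 leaky integrate-and-fire (LIF) point neurons arranged
in four layers (L2/3, L4, L5, L6) and four cell classes: excitatory (Exc)
neurons and parvalbumin- (PV), somatostatin- (SOM) and vasoactive
intestinal peptide-expressing (VIP) interneurons. VIP cells overwhelmingly
reside in L2/3, and connectivity data for deep-layer VIP cells are scarce,
so all VIP cells form a single L2/3 population; the column therefore has
13 populations.

Each neuron obeys

$$\tau_m \frac{dV}{dt} = -(V - V_{rest}) + R_m (I_{exc}(t) + I_{inh}(t)),$$

with exponentially decaying postsynaptic currents (PSCs):
$\tau_{syn}\,dI/dt = -I$, with $\tau_{syn} = 2$ ms for excitatory and 4 ms
for inhibitory inputs. A spike is emitted when $V \ge V_{th}$; the
potential is reset and clamped for an absolute refractory period of
2.0 ms. Subthreshold integration uses exact exponential propagators on a
fixed 0.1 ms grid, so the step size affects spike-time discretization
only, not subthreshold values.

### Neuron parameters

Membrane parameters per cell class and layer group are in vitro patch
values; supragranular values serve L2/3 and L4, infragranular values L5
and L6. Membrane time constants are adjusted to the awake state by the
reported Down-to-Up-state reductions in membrane resistance (50.9% for
excitatory, 4.9% for inhibitory cells), implemented by
`adjust_membrane_time_constant()`. The adjusted values are reported at
one decimal; for L2/3-L4 PV the adopted literature table prints 3.0 ms
although 3.1 x 0.951 rounds to 2.9 — the printed value is transcribed
as-is and the discrepancy documented in the parameter file. No reset
potential is stated in the source data; since the model has no
adaptation, `V_reset = V_rest` per population (configurable).

### Synapses

Synaptic weights are defined as PSP amplitudes first (intracortical EPSPs
0.5 mV, IPSPs -2.0 mV, thalamic EPSPs 0.49 mV, halved for SOM targets)
and converted to the PSC amplitude that produces exactly that peak
deflection in the target neuron:

$$PSC = \frac{C_m (a - 1)\, PSP}{\tau_{syn}\left(a^{1/(1-a)} - a^{a/(1-a)}\right)},
\qquad a = \tau_{syn} / \tau_m .$$

The expression is 0/0 at $a = 1$; the implementation switches to the
analytic limit $C_m e \cdot PSP/\tau_{syn}$ there (the limit is exact, and
continuity at $a = 1 \pm 10^{-6}$ is property-tested). Intracortical and
thalamic PSPs and all delays are log-normally distributed; the package
moment-matches the stated linear-space mean and SD. Inhibitory magnitudes
are sampled log-normally and then negated, since log-normal support is
positive. Delays are rounded to the 0.1 ms grid with a one-step minimum,
as fixed-step event delivery requires grid-aligned times.

### Connectivity

Connections are pairwise Bernoulli per ordered neuron pair with
projection-specific probabilities: autapses are allowed, multapses are
not (potential multiple contacts are absorbed into the unitary weight).
Experimental connection probabilities measured over a limited lateral
sampling range are re-integrated to the model footprint under an
exponential lateral decay kernel (`derive_model_probability()`); the
decay length is a configuration parameter (default 160 um, a plausible
cortical value), and entries whose sampling range is unknown are taken to
refer to the model footprint directly, making the provenance of every
entry explicit. Missing entries are completed by fixed rules: Exc->PV
copies PV->Exc within a layer (Exc-PV pairs reciprocate with high
probability); L5 Exc->SOM, SOM->Exc and SOM->SOM are L2/3-L4 averages;
L6 intra-layer entries other than Exc->Exc copy L5.

The packaged probability and short-term-plasticity matrices are
*synthetic approximate transcriptions*: the published matrices exist only
as figures, so the packaged files keep every value the accompanying text
prints exactly (L2/3 SOM->PV 11.81%, L4 SOM->PV 36.30%, L4 SOM->Exc
19.8%, the thalamic rules) and fill the remainder with
literature-plausible stand-ins, flagged as such in the file headers.
Quantitative conclusions that depend on the exact unpublished entries
should not be drawn from the packaged defaults; both files are plain TSV
and can be replaced wholesale.

### Short-term plasticity

STP follows the Tsodyks model with release parameter $U$, facilitation
time constant $F$ and depression time constant $D$. Between spikes the
release variable $u$ decays toward 0 with $\tau = F$ and resources $x$
recover toward 1 with $\tau = D$; at each spike (including the first)
$u \leftarrow u + U(1-u)$ is applied before release, the transmitted
amplitude is $w\,u\,x$, then $x \leftarrow x(1-u)$. With $u$ initialized
to 0 the first spike releases exactly $w U$. Published Tsodyks variants
differ in whether $u$ relaxes toward 0 or toward $U$; the variant is
selectable (`stp_variant = "decay_to_U"`) for cross-checks, and
$F = 0$ / $D = 0$ mean exact instantaneous relaxation rather than a
division by zero.

Parameters are fitted to normalized PSP-amplitude trains by exhaustive
grid search (U: 0.05-1.0 step 0.05; F, D: 0-1000 ms step 20 ms, i.e.
52,020 points), minimizing the RMSE between simulated and observed
normalized amplitudes. Where the source experiments subtracted the
overlapping tail of preceding PSPs before measuring, the same subtraction
is applied to the simulation; membrane linearity then makes the
normalized amplitudes exactly proportional to $u_n x_n$, which the fitter
exploits (the non-subtracted "onset" mode measures peaks on the
superposed trace instead). Ties are broken deterministically — smallest
RMSE, then smallest U, F, D — because flat or short trains are genuinely
degenerate.

With STP the effective weights drift, so each plastic projection's static
weight is rescaled such that, with the presynaptic neuron firing at its
measured static-model resting rate with fixed inter-spike intervals for
5 s, the final transmitted amplitude is within 0.1 pA of the static
target PSC (`calibrate_weight_scaling()`, proportional updates, at most
100 iterations). Fixed-ISI trains are used deliberately; the factors
depend on measured rates and hence on the seed of the static run that
produced them. The transient thalamic input cannot be calibrated against
a steady state; its weights are instead scaled by $1/u$ so the first
transmitted amplitude equals the static weight.

### Inputs

*Background.* One independent homogeneous Poisson source per neuron with
fixed 0.5 mV EPSPs, 0.1 ms delay, and a cell-type-specific
(layer-independent) rate $r_{bg}$; it is present in every simulation.

*Cell-type-specific stimulation.* An additional Poisson input (0.5 mV
EPSPs) to one population, gated 1 s on / 1 s off, 20 cycles per rate
level, nine levels including zero. The exact nonzero levels are not fully
published; the default is eight equally spaced levels up to 1000 spikes/s
for Exc and PV and up to 200 spikes/s for SOM and VIP, consistent with
the levels that are quoted (125, 200, 250, 375, 1000), and fully
overridable.

*Thalamic input.* The VPM barreloid is sized from the column:
6448 / 56 (S1:VPM ratio) = 115, doubled to 230 to compensate for
multi-whisker receptive fields. Each thalamic neuron draws an independent
inhomogeneous Poisson realization (thinning against the profile maximum)
of a shared log-normal rate time course
$r(t) = A\,e^{-(\ln(t-t_0)-\mu)^2/(2\sigma^2)}/(t-t_0)$, repeated every
second. The packaged profile parameters are synthetic stand-ins for a
digitized experimental curve (peak ~150 spikes/s near 5 ms). Thalamic
axons target Exc and PV in all layers, SOM only in L4 at half probability
and weight, and never VIP.

### Background-rate calibration

The four $r_{bg}$ values are the model's only free parameters. They are
optimized by a two-stage exhaustive grid scan (coarse step 500 spikes/s,
then 100 spikes/s around the coarse optimum) minimizing the
root-mean-square percentage error (RMSPE) of the mean rates of the seven
L2/3 and L4 populations against in vivo reference rates; L5 and L6 are
excluded from the objective. The packaged Base calibration was produced
with this package's own optimizer at reduced instance counts; the
resulting rates order as PV > Exc > VIP > SOM, matching the reported
plausibility pattern for long-range input strengths. Because the packaged
connectivity matrix is partly a stand-in, the calibrated state
approximates the reference rates but should be re-optimized whenever the
connectivity file is replaced.

## Analysis definitions

* Population rates: per-neuron spike count over the analysis window;
  summaries across neurons (and instances).
* Pairwise spike-count correlation: per layer, all cell types pooled,
  neurons with no spikes excluded, 200 sampled neurons, Pearson
  correlation of 10 ms binned counts over all distinct pairs.
* CV ISI: neurons below 1 spikes/s excluded; separate 200-neuron sample;
  SD/mean of inter-spike intervals per neuron, averaged.
* PSTH: 0.5 ms bins, counts / (bin x neurons x repeats), peak searched in
  0-50 ms after onset, ties to the earliest bin. Peak RMSEs against a
  reference table use zero as the VIP amplitude criterion and exclude VIP
  from the time comparison.
* Stimulus responses: rates over the last 500 ms of each on-window,
  averaged over repeats, normalized per instance to the zero level, and
  tested against 1 with a two-tailed one-sample t-test across instances.
  Zero-variance samples return p = 1 with a flag; instances with a zero
  baseline are flagged and excluded.

The asynchronous-irregular (AI) criteria shipped with the package
(bounds on layer-mean correlation and CV ISI) are configuration inputs
emulating an external compilation, not assertions.

## What the synthetic data do and do not show

Every test input is generated in code with known ground truth: PSP trains
come from the exact release recursion (plus optional multiplicative
Gaussian noise), Poisson surrogates exercise the estimators, and the toy
column keeps the 13-population topology at small N. Passing tests
therefore demonstrate that the machinery is self-consistent — parameter
derivations exact, estimators unbiased on their generating models,
simulator reproducible — not that the packaged stand-in matrices equal
the unpublished originals. Statistical checks on the full column (resting
rates near the reference table, inhibition by PV/SOM and disinhibition by
VIP and L4 SOM, the sign flip under halved L4 SOM->PV connectivity) are
run at reduced scale: 1-3 instances, 2-3 stimulus repeats, 15 s resting
simulations, and a 4 s warmup for stimulation runs (transients from the
seeded uniform initial potentials settle well within that at the
calibrated rates). The published protocol sizes (20 instances, 20
repeats, nine levels, 10 s warmup) remain the defaults of
`run_config()` and `stimulus_protocol()`.

## Numerical choices

* Integration: exact propagators, 0.1 ms grid; threshold detected at step
  boundaries without interpolation; refractory clamp holds V at
  `V_reset` while synaptic currents continue to evolve.
* Initial potentials: uniform between `V_rest` and `V_th` per neuron
  (seeded) to avoid synchronous onset artifacts; configurable to all-rest.
* Interneuron apportionment uses largest-remainder rounding (ties by PV,
  SOM, VIP order) so layer totals are conserved exactly.
* The spatial integration of connection probabilities averages the decay
  kernel over pair displacements by deterministic quadrature (triangular
  coordinate-difference densities for rectangles, the closed-form
  distance density for discs); a Monte-Carlo oracle cross-checks it in
  the tests.
* All randomness is seeded: network realization and initial states from
  the build seed (R's RNG), input realizations from the run seed (a
  dedicated mt19937-64 stream inside the engine), sampling steps in the
  analysis from explicit seeds. Identical seeds and configuration
  reproduce spike output bitwise.

## Limitations

The neuron model omits adaptation, conductance synapses and NMDA
components; connectivity is non-spatial once probabilities are derived;
Martinotti/non-Martinotti SOM subtypes, L1 interneurons, higher-order
thalamus and cross-column inputs are out of scope. The packaged
connectivity, STP, thalamic-profile, AI-criteria and reference-peak files
are synthetic approximations as described above; exact numeric agreement
with the original published matrices is neither claimed nor testable from
the packaged data.
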