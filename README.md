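# barrelsim

Spiking-network simulator of a mouse barrel-cortex (S1) column with
layer-resolved excitatory neurons and the three major inhibitory
interneuron classes — PV, SOM and VIP cells. The column holds 6448 leaky
integrate-and-fire (LIF) neurons in 13 populations across L2/3-L6, wired
by pairwise Bernoulli connectivity with log-normally distributed synaptic
weights and delays, driven by per-neuron Poisson background input, and
optionally equipped with Tsodyks short-term plasticity (STP: release
parameter U, facilitation time constant F, depression time constant D)
per projection. It is aimed at computational neuroscientists studying
cell-type-specific inhibition and disinhibition (e.g. the VIP→SOM→Exc
pathway), layer-specific SOM roles, and STP effects on transient
responses.

The package covers the full workflow:

* **Parameter derivation** — in vitro → in vivo membrane time-constant
  adjustment, PSP→PSC conversion
  `PSC = C_m (a−1) PSP / (τ_syn (a^{1/(1−a)} − a^{a/(1−a)}))` with
  `a = τ_syn/τ_m`, interneuron apportionment, spatial re-integration of
  connection probabilities under an exponential lateral decay.
* **STP calibration** — exhaustive (U, F, D) grid fitting to normalized
  PSP-amplitude trains and weight rescaling so the STP model's steady
  state matches the static model.
* **Simulation** — a fixed-step (0.1 ms) exact-propagator engine (Rcpp)
  with background, gated cell-type-specific stimulation, and a transient
  230-neuron thalamic (VPM) input with an inhomogeneous-Poisson
  log-normal rate time course.
* **Calibration & analysis** — two-stage grid optimization of background
  rates against reference firing rates (RMSPE objective), population
  rates, pairwise spike-count correlations, CV ISI, PSTHs with peak
  extraction, and normalized stimulus-response curves with t-tests.

The packaged connection-probability and STP matrices are *synthetic
approximate transcriptions* (the originals were published as figures);
values printed in accompanying text are exact, the rest are
literature-plausible stand-ins, and the files say so in their headers.
See the vignette (`vignettes/barrel-microcircuit.Rmd`) for the model,
its assumptions and limitations.

## Worked example: fit STP parameters and calibrate a weight

```r
library(barrelsim)

pops <- build_population_table(bc_config())
pops
#> Column populations: 13 populations, 6448 neurons
#>          layer type    n tau_m   c_m v_rest  v_th
#> L2/3 Exc  L2/3  Exc 1691   5.2 229.8  -67.4 -41.5
#> L2/3 PV   L2/3   PV   90   3.0  93.9  -66.4 -41.6
#> ...

# a facilitating-then-depressing synthetic PSP train (ground truth known)
obs <- make_psp_train_fixture(list(U = 0.30, F = 260, D = 420),
                              rate = 10, n_spikes = 12)
round(obs$normalized_amplitudes, 3)
#>  [1] 1.000 1.127 0.932 0.766 0.678 0.639 0.622 0.615 0.612 0.611 0.610 0.610

fit_stp_parameters(obs)
#> STP fit: U = 0.30, F = 260 ms, D = 420 ms (RMSE 0, subtraction mode)

# weight scaling for a depressing projection firing at 10 spikes/s
calibrate_weight_scaling(list(U = 0.5, F = 0, D = 300),
                         presyn_rate = 10, target_psc = 120)$factor
#> [1] 4.5277
```

The train rises (facilitation, F = 260 ms) then settles below 1
(depression, D = 420 ms); the grid fit recovers the generating triple
with zero error. The scaling factor 4.53 is the amount by which the
static weight must be raised so that, at a 10 spikes/s steady state, the
depressed effective amplitude equals the 120 pA static target.

Network-level runs follow the same pattern:

```r
rc <- run_config(variant = "Base", n_instances = 2)
rs <- run_resting_state(rc, duration = 15000)   # rates, correlations, CV ISI
prot <- stimulus_protocol("L2/3 SOM")            # 9 levels up to 200 spikes/s
st <- run_cell_type_stimulation(rc, prot)        # normalized responses + tests
```

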