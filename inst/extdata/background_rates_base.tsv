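# Calibrated cell-type-specific background Poisson rates (spikes/s),
# layer-independent, for the model with static synapses (r_bg_static, the
# Base configuration) and with short-term plasticity (r_bg_stp, Base-STP;
# defaults to the static optimum because the STP weight scaling is
# designed to reproduce the static resting state). Produced with the
# package's background-rate optimization against the L2/3 and L4
# reference firing rates; the rates order as PV > Exc > VIP > SOM. These
# values are tied to the packaged (partly synthetic) connectivity matrix
# and should be re-optimized if that file is replaced.
type	r_bg_static	r_bg_stp
Exc	4400	4400
PV	7000	7000
SOM	1900	1900
VIP	2900	2900
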