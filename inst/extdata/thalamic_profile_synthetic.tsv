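# SYNTHETIC APPROXIMATE parameters of the log-normal firing-rate time
# course of the thalamic (VPM) touch response,
#   r(t) = A * exp(-(log(t - t0) - mu)^2 / (2 sigma^2)) / (t - t0)
# for t > t0 and 0 otherwise, t in ms and r in spikes/s. The original curve
# was fitted to digitized experimental points that are not redistributable;
# these values emulate a transient peaking near 150 spikes/s around 5 ms
# after touch and decayed by ~30 ms.
param	value
A	750
t0	1.0
mu	1.7918
sigma	0.6
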