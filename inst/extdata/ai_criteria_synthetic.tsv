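# SYNTHETIC APPROXIMATE asynchronous-irregular (AI) state criteria for the
# resting-state evaluation: bounds on layer-mean pairwise spike-count
# correlation (awake sessions) and CV ISI (awake sessions and anesthetized
# Up states). The published numeric criteria come from an external
# compilation that is not redistributable; these stand-ins emulate its
# structure and are configuration inputs, not assertions.
criterion	value
corr_awake_min	0.0005
corr_awake_max	0.01
cv_isi_awake_min	1.00
cv_isi_awake_max	1.35
cv_isi_anesth_up	0.55
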