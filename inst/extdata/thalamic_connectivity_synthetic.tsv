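# SYNTHETIC APPROXIMATE thalamocortical (VPM barreloid) connection
# probabilities in percent for Exc and PV targets in L4-L6. Derived rows
# are computed at build time: L2/3 Exc and PV probabilities equal the L4
# values times the configured L2/3-to-L4 thalamocortical synapse ratio, and
# the L4 SOM probability (the only SOM target) equals 50% of the L4 Exc
# value. VIP cells receive no thalamic input.
layer	type	p
L4	Exc	43.0
L4	PV	50.0
L5	Exc	10.0
L5	PV	15.0
L6	Exc	8.0
L6	PV	10.0
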