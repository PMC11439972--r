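# SYNTHETIC APPROXIMATE reference PSTH peak amplitudes (spikes/s) and peak
# times (ms after stimulus onset) of touch-evoked cortical responses, used
# by the peak-RMSE comparison. The published values were digitized from an
# external figure and are not redistributable; these stand-ins emulate the
# qualitative pattern (PV earliest and largest, then Exc, then SOM; no VIP
# response). The VIP amplitude criterion is zero and VIP is excluded from
# the time comparison by the RMSE rules.
layer	type	a_peak	t_peak
L2/3	Exc	25	12.0
L2/3	PV	60	10.0
L2/3	SOM	20	16.0
L2/3	VIP	0	NA
L4	Exc	35	10.0
L4	PV	90	8.0
L4	SOM	15	14.0
L5	Exc	30	11.0
L5	PV	70	9.0
L5	SOM	12	15.0
L6	Exc	15	12.0
L6	PV	40	10.0
L6	SOM	10	16.0
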