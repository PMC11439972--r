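# Synapse classes: PSP amplitude statistics (mV), PSC decay time constant
# (ms) and transmission delay statistics (ms). psp_sd = 0 and delay_sd = 0
# denote fixed (non-random) values.
class	sign	psp_mean	psp_sd	tau_syn	delay_mean	delay_sd
exc	1	0.5	0.5	2	1.36	0.51
inh	-1	2.0	2.0	4	1.43	1.09
th	1	0.49	0.13	2	1.72	0.73
th_som	1	0.245	0.065	2	1.72	0.73
bg	1	0.5	0	2	0.1	0
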