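# Layer-wise excitatory and inhibitory neuron counts for the modeled
# mouse C2 barrel column (one barrel, 200 x 300 um footprint).
layer	n_exc	n_inh
L2/3	1691	231
L4	1656	140
L5	1095	221
L6	1288	126
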