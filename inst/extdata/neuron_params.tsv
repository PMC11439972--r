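# Cell-type- and layer-group-specific LIF neuron parameters (in vitro).
# tau_m_invitro in ms, C_m in pF, potentials in mV. The in vivo membrane
# time constant is obtained by reducing membrane resistance by the
# cell-class-specific fraction (see exc/inh reduction in the configuration);
# tau_m_printed is the one-decimal literature value adopted by the model
# (for L2/3-L4 PV the printed value 3.0 differs from the recomputed 2.9 and
# is transcribed as-is).
group	tau_m_invitro	tau_m_printed	c_m	v_rest	v_th
L23L4_Exc	10.5	5.2	229.8	-67.4	-41.5
L23L4_PV	3.1	3.0	93.9	-66.4	-41.6
L23L4_SOM	11.8	11.2	123.3	-59.9	-41.8
VIP	10.9	10.4	86.5	-65.7	-43.7
L5L6_Exc	12.1	5.9	269.2	-63.2	-45.2
L5L6_PV	4.0	3.8	81.0	-67.1	-42.3
L5L6_SOM	11.7	11.1	146.8	-63.2	-48.1
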