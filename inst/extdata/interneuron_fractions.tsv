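# Relative quantities of PV, SOM and VIP interneurons per layer.
# APPROXIMATE: the original per-layer fractions were digitized from a
# published figure that is not redistributable here; these defaults are the
# per-layer relative counts implied by the model's own population table and
# reproduce it exactly under largest-remainder apportionment. Override via
# the configuration if independent fraction estimates are available.
layer	f_pv	f_som	f_vip
L2/3	90	74	67
L4	85	48	7
L5	109	105	7
L6	56	66	4
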