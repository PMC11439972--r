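# SYNTHETIC APPROXIMATE transcription of the cell-type-specific Tsodyks
# short-term-plasticity parameter matrix. The original best-fit matrix was
# published as a figure and is not redistributable here; these entries
# preserve its qualitative structure (depressing Exc->Exc, Exc->PV, PV->*
# and thalamocortical->PV projections; facilitating Exc->SOM and
# thalamocortical->SOM projections; static VIP-related projections) with
# literature-plausible magnitudes placed on the fitting grid (U multiple of
# 0.05; F, D multiples of 20 ms). Layer NA means the row applies to every
# layer; layer-specific rows take precedence. Projections with no matching
# row remain static.
source_type	target_type	source_layer	target_layer	U	F	D
Exc	Exc	L2/3	L2/3	0.45	20	300
Exc	Exc	L4	L2/3	0.50	0	280
Exc	Exc	L4	L4	0.55	20	260
Exc	Exc	L2/3	L5	0.50	20	300
Exc	Exc	L5	L5	0.50	40	400
Exc	Exc	L5	L6	0.50	20	340
Exc	Exc	L6	L6	0.45	20	300
Exc	PV	NA	NA	0.60	20	400
Exc	SOM	NA	NA	0.10	400	100
PV	Exc	NA	NA	0.40	20	300
PV	PV	NA	NA	0.40	20	300
PV	SOM	NA	NA	0.40	20	300
SOM	Exc	NA	NA	0.30	100	400
SOM	PV	NA	NA	0.30	100	400
Exc_th	Exc	NA	NA	0.50	0	280
Exc_th	PV	NA	NA	0.70	0	140
Exc_th	SOM	NA	NA	0.15	300	100
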