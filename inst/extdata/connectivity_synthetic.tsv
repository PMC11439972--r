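# SYNTHETIC APPROXIMATE transcription of the experimental / estimated
# connection-probability inputs (percent) from which the full 13 x 13
# projection matrix is assembled. The original matrix was published as a
# figure and is not redistributable; entries anchored by printed text
# (L2/3 SOM->PV 11.81, L4 SOM->PV 36.30, L4 SOM->Exc 19.8) are exact,
# the remainder are literature-plausible stand-ins. range_um = NA means
# the value already refers to the model footprint (no spatial
# re-integration). Absent intra-layer entries are completed by the
# assembly rules (Exc<->PV reciprocity; L5 SOM-related entries as
# L2/3-L4 averages; L6 copies of L5).
source_layer	source_type	target_layer	target_type	p_exp	range_um	provenance
L2/3	Exc	L2/3	Exc	9	NA	paired-recording
L2/3	Exc	L2/3	PV	13	NA	paired-recording
L2/3	Exc	L2/3	SOM	15	NA	paired-recording
L2/3	Exc	L2/3	VIP	7	NA	paired-recording
L2/3	PV	L2/3	Exc	13	NA	paired-recording
L2/3	PV	L2/3	PV	25	NA	paired-recording
L2/3	PV	L2/3	SOM	4	NA	assumption
L2/3	PV	L2/3	VIP	5	NA	assumption
L2/3	SOM	L2/3	Exc	15	NA	paired-recording
L2/3	SOM	L2/3	PV	11.81	NA	paired-recording
L2/3	SOM	L2/3	SOM	2	NA	assumption
L2/3	SOM	L2/3	VIP	15	NA	paired-recording
L2/3	VIP	L2/3	Exc	1	NA	assumption
L2/3	VIP	L2/3	PV	2	NA	assumption
L2/3	VIP	L2/3	SOM	20	NA	paired-recording
L2/3	VIP	L2/3	VIP	2	NA	assumption
L4	Exc	L4	Exc	17	NA	paired-recording
L4	Exc	L4	SOM	12	NA	paired-recording
L4	PV	L4	Exc	40	NA	paired-recording
L4	PV	L4	PV	30	NA	paired-recording
L4	PV	L4	SOM	20	NA	paired-recording
L4	SOM	L4	Exc	19.8	NA	paired-recording
L4	SOM	L4	PV	36.3	NA	paired-recording
L4	SOM	L4	SOM	8	NA	assumption
L5	Exc	L5	Exc	13	NA	paired-recording
L5	PV	L5	Exc	33	NA	paired-recording
L5	PV	L5	PV	25	NA	paired-recording
L5	PV	L5	SOM	10	NA	assumption
L5	SOM	L5	PV	10	NA	paired-recording
L6	Exc	L6	Exc	8	NA	paired-recording
L2/3	Exc	L4	Exc	1	NA	paired-recording
L2/3	Exc	L5	Exc	9	NA	paired-recording
L2/3	Exc	L6	Exc	1.5	NA	paired-recording
L4	Exc	L2/3	Exc	13	NA	paired-recording
L4	Exc	L5	Exc	6	NA	paired-recording
L4	Exc	L6	Exc	1	NA	paired-recording
L5	Exc	L2/3	Exc	2.5	NA	paired-recording
L5	Exc	L4	Exc	1.5	NA	paired-recording
L5	Exc	L6	Exc	3	NA	paired-recording
L6	Exc	L2/3	Exc	0.5	NA	paired-recording
L6	Exc	L4	Exc	1	NA	paired-recording
L6	Exc	L5	Exc	2	NA	paired-recording
L2/3	Exc	L4	PV	1	NA	morphology-estimate
L2/3	Exc	L4	SOM	1	NA	morphology-estimate
L2/3	Exc	L5	PV	4	NA	morphology-estimate
L2/3	Exc	L5	SOM	3	NA	morphology-estimate
L2/3	Exc	L6	PV	1	NA	morphology-estimate
L2/3	Exc	L6	SOM	1	NA	morphology-estimate
L4	Exc	L2/3	PV	8	NA	morphology-estimate
L4	Exc	L2/3	SOM	6	NA	morphology-estimate
L4	Exc	L2/3	VIP	4	NA	morphology-estimate
L4	Exc	L5	PV	3	NA	morphology-estimate
L4	Exc	L5	SOM	2	NA	morphology-estimate
L4	Exc	L6	PV	1	NA	morphology-estimate
L4	Exc	L6	SOM	1	NA	morphology-estimate
L5	Exc	L2/3	PV	1.5	NA	morphology-estimate
L5	Exc	L2/3	SOM	1.5	NA	morphology-estimate
L5	Exc	L2/3	VIP	1	NA	morphology-estimate
L5	Exc	L4	PV	1	NA	morphology-estimate
L5	Exc	L4	SOM	1	NA	morphology-estimate
L5	Exc	L6	PV	3	NA	morphology-estimate
L5	Exc	L6	SOM	2	NA	morphology-estimate
L6	Exc	L2/3	PV	0.5	NA	morphology-estimate
L6	Exc	L2/3	SOM	0.5	NA	morphology-estimate
L6	Exc	L2/3	VIP	0.5	NA	morphology-estimate
L6	Exc	L4	PV	1	NA	morphology-estimate
L6	Exc	L4	SOM	0.5	NA	morphology-estimate
L6	Exc	L5	PV	1	NA	morphology-estimate
L6	Exc	L5	SOM	1	NA	morphology-estimate
L2/3	PV	L4	Exc	1	NA	morphology-estimate
L2/3	PV	L4	PV	0.5	NA	morphology-estimate
L2/3	PV	L4	SOM	0.5	NA	morphology-estimate
L2/3	PV	L5	Exc	1	NA	morphology-estimate
L2/3	PV	L5	PV	0.5	NA	morphology-estimate
L2/3	PV	L5	SOM	0.5	NA	morphology-estimate
L2/3	PV	L6	Exc	1	NA	morphology-estimate
L2/3	PV	L6	PV	0.5	NA	morphology-estimate
L2/3	PV	L6	SOM	0.5	NA	morphology-estimate
L2/3	SOM	L4	Exc	1.5	NA	morphology-estimate
L2/3	SOM	L4	PV	1	NA	morphology-estimate
L2/3	SOM	L4	SOM	0.5	NA	morphology-estimate
L2/3	SOM	L5	Exc	1.5	NA	morphology-estimate
L2/3	SOM	L5	PV	1	NA	morphology-estimate
L2/3	SOM	L5	SOM	0.5	NA	morphology-estimate
L2/3	SOM	L6	Exc	1.5	NA	morphology-estimate
L2/3	SOM	L6	PV	1	NA	morphology-estimate
L2/3	SOM	L6	SOM	0.5	NA	morphology-estimate
L2/3	VIP	L4	Exc	0.5	NA	morphology-estimate
L2/3	VIP	L4	PV	0.5	NA	morphology-estimate
L2/3	VIP	L4	SOM	1.5	NA	morphology-estimate
L2/3	VIP	L5	Exc	0.5	NA	morphology-estimate
L2/3	VIP	L5	PV	0.5	NA	morphology-estimate
L2/3	VIP	L5	SOM	1.5	NA	morphology-estimate
L2/3	VIP	L6	Exc	0.5	NA	morphology-estimate
L2/3	VIP	L6	PV	0.5	NA	morphology-estimate
L2/3	VIP	L6	SOM	1.5	NA	morphology-estimate
L4	PV	L2/3	Exc	1	NA	morphology-estimate
L4	PV	L2/3	PV	0.5	NA	morphology-estimate
L4	PV	L2/3	SOM	0.5	NA	morphology-estimate
L4	PV	L2/3	VIP	0.5	NA	morphology-estimate
L4	PV	L5	Exc	1	NA	morphology-estimate
L4	PV	L5	PV	0.5	NA	morphology-estimate
L4	PV	L5	SOM	0.5	NA	morphology-estimate
L4	PV	L6	Exc	1	NA	morphology-estimate
L4	PV	L6	PV	0.5	NA	morphology-estimate
L4	PV	L6	SOM	0.5	NA	morphology-estimate
L4	SOM	L2/3	Exc	1.5	NA	morphology-estimate
L4	SOM	L2/3	PV	1	NA	morphology-estimate
L4	SOM	L2/3	SOM	0.5	NA	morphology-estimate
L4	SOM	L2/3	VIP	1	NA	morphology-estimate
L4	SOM	L5	Exc	1.5	NA	morphology-estimate
L4	SOM	L5	PV	1	NA	morphology-estimate
L4	SOM	L5	SOM	0.5	NA	morphology-estimate
L4	SOM	L6	Exc	1.5	NA	morphology-estimate
L4	SOM	L6	PV	1	NA	morphology-estimate
L4	SOM	L6	SOM	0.5	NA	morphology-estimate
L5	PV	L2/3	Exc	1	NA	morphology-estimate
L5	PV	L2/3	PV	0.5	NA	morphology-estimate
L5	PV	L2/3	SOM	0.5	NA	morphology-estimate
L5	PV	L2/3	VIP	0.5	NA	morphology-estimate
L5	PV	L4	Exc	1	NA	morphology-estimate
L5	PV	L4	PV	0.5	NA	morphology-estimate
L5	PV	L4	SOM	0.5	NA	morphology-estimate
L5	PV	L6	Exc	1	NA	morphology-estimate
L5	PV	L6	PV	0.5	NA	morphology-estimate
L5	PV	L6	SOM	0.5	NA	morphology-estimate
L5	SOM	L2/3	Exc	1.5	NA	morphology-estimate
L5	SOM	L2/3	PV	1	NA	morphology-estimate
L5	SOM	L2/3	SOM	0.5	NA	morphology-estimate
L5	SOM	L2/3	VIP	1	NA	morphology-estimate
L5	SOM	L4	Exc	1.5	NA	morphology-estimate
L5	SOM	L4	PV	1	NA	morphology-estimate
L5	SOM	L4	SOM	0.5	NA	morphology-estimate
L5	SOM	L6	Exc	1.5	NA	morphology-estimate
L5	SOM	L6	PV	1	NA	morphology-estimate
L5	SOM	L6	SOM	0.5	NA	morphology-estimate
L6	PV	L2/3	Exc	1	NA	morphology-estimate
L6	PV	L2/3	PV	0.5	NA	morphology-estimate
L6	PV	L2/3	SOM	0.5	NA	morphology-estimate
L6	PV	L2/3	VIP	0.5	NA	morphology-estimate
L6	PV	L4	Exc	1	NA	morphology-estimate
L6	PV	L4	PV	0.5	NA	morphology-estimate
L6	PV	L4	SOM	0.5	NA	morphology-estimate
L6	PV	L5	Exc	1	NA	morphology-estimate
L6	PV	L5	PV	0.5	NA	morphology-estimate
L6	PV	L5	SOM	0.5	NA	morphology-estimate
L6	SOM	L2/3	Exc	1.5	NA	morphology-estimate
L6	SOM	L2/3	PV	1	NA	morphology-estimate
L6	SOM	L2/3	SOM	0.5	NA	morphology-estimate
L6	SOM	L2/3	VIP	1	NA	morphology-estimate
L6	SOM	L4	Exc	1.5	NA	morphology-estimate
L6	SOM	L4	PV	1	NA	morphology-estimate
L6	SOM	L4	SOM	0.5	NA	morphology-estimate
L6	SOM	L5	Exc	1.5	NA	morphology-estimate
L6	SOM	L5	PV	1	NA	morphology-estimate
L6	SOM	L5	SOM	0.5	NA	morphology-estimate
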