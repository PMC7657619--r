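# Reference dataset: glycolytic and related enzyme activities in cell extracts
# from the same cellobiose-limited chemostats (umol/mg protein/min, means;
# "<0.01" = below detection). Data-only fixture: no computation in this
# package consumes it.
enzyme	cofactor	cthermocellum	tsaccharolyticum
glucokinase	GTP	0.71	0.07
glucokinase	ATP	0.06	0.84
glucokinase	PEP	<0.01	<0.01
phosphofructokinase	PPi	1.20	<0.01
phosphofructokinase	ATP	<0.01	0.55
phosphoglycerate_kinase	GDP	2.37	0.35
phosphoglycerate_kinase	ADP	3.21	6.70
gap_dehydrogenase	NAD	3.86	11.68
gap_dehydrogenase	NADP	<0.01	0.07
pep_carboxykinase	ADP	0.16	0.49
pep_carboxykinase	GDP	4.80	0.11
pep_carboxykinase	Pi	<0.01	<0.01
pyruvate_kinase	ADP	<0.01	0.65
pyruvate_phosphate_dikinase	AMP+PPi	0.19	0.86
malate_dehydrogenase	NADH	3.79	<0.01
malate_dehydrogenase	NADPH	0.24	0.07
malic_enzyme	NAD	0.05	0.06
malic_enzyme	NADP	2.78	0.07
glucose_6_phosphate_dehydrogenase	NADP	<0.01	0.03
6_phosphogluconate_dehydrogenase	NADP	<0.01	0.05
isocitrate_dehydrogenase	NAD	<0.01	<0.01
isocitrate_dehydrogenase	NADP	1.05	0.91
glutamate_dehydrogenase	NAD	<0.01	<0.01
glutamate_dehydrogenase	NADP	2.34	<0.01
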