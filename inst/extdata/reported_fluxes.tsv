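# Reference dataset: published specific fluxes (mmol/g cell N/h; amino acid
# and protein fluxes mg/g cell N/h) for carbon-limited wild type,
# nitrogen-limited wild type (0.15 g urea/liter) and a phosphotransacetylase
# deletion strain. The nitrogen-limited and deletion columns lack underlying
# concentration tables, so only ratios against the carbon-limited column are
# computable.
# NOTE: the printed q_cellobiose (4.66) is not reconcilable with
# D x feed / cell N under any molar-mass convention (that gives ~13.6);
# it is carried as printed and excluded from quantitative checks.
component	carbon_limited	nitrogen_limited_urea015	pta_deletion	unit
cell_nitrogen	102.0	40.4	71.8	mg N/liter
cell_carbon	337.3	183.3	259.9	mg C/liter
q_cellobiose	4.66	9.32	6.61	mmol/g N/h
q_acetate	17.34	30.36	0.76	mmol/g N/h
q_ethanol	14.89	16.35	25.62	mmol/g N/h
q_formate	5.15	7.97	1.66	mmol/g N/h
q_lactate	0.38	3.32	1.39	mmol/g N/h
q_excreted_pyruvate	0.17	8.56	18.19	mmol/g N/h
q_total_pyruvate	33.03	63.88	51.08	mmol/g N/h
q_valine	0.13	2.64	2.56	mmol/g N/h
q_excreted_amino_acids	89.04	579.64	474.60	mg/g N/h
q_supernatant_protein	101.42	60.04	51.67	mg/g N/h
q_nitrogen_uptake	9.75	14.26	12.89	mmol/g N/h
carbon_recovery	81.8	70.6	79.1	%
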