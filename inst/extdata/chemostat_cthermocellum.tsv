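# Reference dataset: cellobiose-limited chemostat steady state, D = 0.1 1/h, pH 7.0, 55 C
# Concentrations are mg/liter; ND = not detected (below detection limit)
# Declared amino-acid elemental totals are carried as reported; the nitrogen
# total is not reproducible by elemental summation over the listed species.
# organism: Clostridium thermocellum
# dilution_rate: 0.1
# feed_nitrogen: 523.7
# aa_total_carbon: 40.5
# aa_total_nitrogen: 20.6
species	concentration_mg_per_l	role
cellobiose	4757.2	feed
cellobiose	ND	residual
acetate	1062.4	product
ethanol	699.6	product
lactate	35.3	product
formate	241.8	product
glucose	20.2	product
pyruvate	15.4	product
isobutanol	25.3	product
cell_carbon	337.3	cell_c
cell_nitrogen	102.0	cell_n
protein	103.5	protein
alanine	15.0	amino_acid
asparagine	0.5	amino_acid
aspartic_acid	1.7	amino_acid
glutamic_acid	30.0	amino_acid
glutamine	0.3	amino_acid
histidine	0.0	amino_acid
isoleucine	4.0	amino_acid
leucine	3.0	amino_acid
lysine	6.5	amino_acid
methionine	0.0	amino_acid
phenylalanine	1.0	amino_acid
proline	4.3	amino_acid
serine	4.6	amino_acid
threonine	4.0	amino_acid
tryptophan	0.3	amino_acid
tyrosine	0.6	amino_acid
valine	15.0	amino_acid
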