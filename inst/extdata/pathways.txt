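# Reaction library: pyrophosphate-dependent glycolysis and associated
# symbolic stoichiometry. Water is implicit. One reaction per line,
# "name: equation"; load with read_reactions().
pp_glycolysis_net: glucose + 5 ADP + 3 PPi -> 2 pyruvate + 5 ATP + Pi
ppdk: PEP + AMP + PPi -> pyruvate + ATP + Pi
adenylate_kinase: 2 ADP -> AMP + ATP
ppi_generator: ATP + Pi -> ADP + PPi
pep_carboxykinase: PEP + CO2 + GDP -> OAA + GTP
malate_dehydrogenase: OAA + NADH -> malate + NAD
malic_enzyme: malate + NADP -> pyruvate + CO2 + NADPH
nfnab: ferredoxinred + NADH + 2 NADP -> ferredoxinox + NAD + 2 NADPH
trna_charging_and_bond: aa1 + aa2 + 2 GTP + ATP -> aa1-aa2 + 2 GDP + 2 Pi + AMP + PPi
soluble_pyrophosphatase: PPi -> 2 Pi
ppi_pfk: 2 F6P + 2 PPi -> 2 FBP + 2 Pi
aldolase_fbp: 2 FBP -> 4 C3P
transketolase_1: F6P + C3P -> C5P + C4P
aldolase_sbp: C4P + C3P -> SBP
ppi_pfk_sbp: SBP + Pi -> C7P + PPi
transketolase_2: C7P + C3P -> 2 C5P
glycogen_cycle_net: ATP + Pi -> ADP + PPi
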