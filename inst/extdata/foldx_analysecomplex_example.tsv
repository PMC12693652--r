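FoldX AnalyseComplex output example (synthetic; energies are the published
wild-type binding free energies of CaM-CaMBD complexes, kcal/mol)
Pdb	Group1	Group2	Interaction Energy
PMCA1a_WT_Repair.pdb	A	B	-48.22
PMCA2a_2b_3b_WT_Repair.pdb	A	B	-61.92
PMCA4b_WT_Repair.pdb	A	B	-59.20
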