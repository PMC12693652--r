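# Default single-nucleotide substitution plan for the 18-residue CaMBD
# window: motif position -> target codons reachable by one base change at
# the second codon position in at least one human PMCA isoform.
"5": [cgg]
"6": [atc, att]
"8": [acc, act]
"14": [gaa, gag, gac]
"18": [tct, tcc]
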