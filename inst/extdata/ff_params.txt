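# polbind molecular-mechanics surrogate parameters.
# vdw <element> <sigma_A> <epsilon_kcal_mol>   (Lorentz-Berthelot combination)
vdw C 3.40 0.086
vdw N 3.25 0.170
vdw O 2.96 0.210
vdw P 3.74 0.200
vdw S 3.56 0.250
# charge <residue 3-letter> <formal charge e>; unlisted residues are neutral.
# Nucleotide backbone charge (-1) sits on the P atom, handled by atom name.
charge ASP -1
charge GLU -1
charge LYS 1
charge ARG 1
charge HIS 0
# constants
coulomb_k 332.06
dna_phosphate_charge -1
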