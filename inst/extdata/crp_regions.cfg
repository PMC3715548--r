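# Default functional regions for the catabolite activator protein (CRP)
# homodimer, author (PDB) numbering, one entry per subunit chain.
# Format: name = chain:start-end

# inter-domain hinge
hinge_A = A:134-138
hinge_B = B:134-138

# flexible site of the cAMP-binding domain (beta4-beta5 flap)
camp_site_A = A:52-58
camp_site_B = B:52-58

# flexible site of the DNA-binding domain
dna_site_A = A:173-176
dna_site_B = B:173-176

# second flexible site of the DNA-binding domain
dna_site2_A = A:154-156
dna_site2_B = B:154-156

# domain spans
dna_domain_A = A:139-209
dna_domain_B = B:139-209
camp_domain_A = A:1-133
camp_domain_B = B:1-133
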