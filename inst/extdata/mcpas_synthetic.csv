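CDR3.beta.aa,Pathology,Antigen.protein,Epitope.peptide,T.Cell.Type,Species
CASSLGQAYEQYF,Epstein Barr virus (EBV),EBNA3A,FLRGRAYGL,CD8,Human
CASSLGQAYEQYF,Epstein Barr virus (EBV),EBNA3A,FLRGRAYGL,CD8,Human
CASSLGQAYEQFF,Epstein Barr virus (EBV),EBNA1,HPVGEADYFEY,CD8,Human
CASSIRSSYEQYF,Influenza,M1,GILGFVFTL,CD8,Human
CASSPGTGELFF,Cytomegalovirus (CMV),pp65,NLVPMVATV,CD8,Human
CASRPGLAGGRPEQYF,Cytomegalovirus (CMV),pp65,NLVPMVATV,CD8,Human
CASSQDRNTGELFF,Celiac disease,Gliadin,,CD4,Human
CASSFSTCSANYGYTF,Multiple sclerosis,MBP,,CD4,Human
CASSLAPGATNEKLFF,Influenza,NP,,CD8,Human
NA,Influenza,M1,GILGFVFTL,CD8,Human
CASS_GQAYEQYF,Epstein Barr virus (EBV),EBNA3A,,CD8,Human
CASSLEGQGFGYTF,Yellow fever virus,NS4B,LLWNGPMAV,CD8,Human
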