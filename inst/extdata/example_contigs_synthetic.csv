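barcode,is_cell,high_confidence,chain,v_gene,j_gene,cdr3,cdr3_nt,productive
AAACCTGAGAAACCAT-1,True,True,TRA,TRAV12-1,TRAJ33,CAVRDSNYQLIW,TGTGCTGTGAGAGATAGCAACTATCAGTTAATCTGG,True
AAACCTGAGAAACCAT-1,True,True,TRB,TRBV7-2,TRBJ2-7,CASSLGQAYEQYF,TGTGCCAGCAGCTTGGGACAGGCTTACGAGCAGTACTTC,True
AAACCTGAGAAGGCCT-1,True,True,TRA,TRAV12-1,TRAJ33,CAVRDSNYQLIW,TGTGCTGTGAGAGATAGCAACTATCAGTTAATCTGG,True
AAACCTGAGAAGGCCT-1,True,True,TRB,TRBV7-2,TRBJ2-7,CASSLGQAYEQYF,TGTGCCAGCAGCTTGGGACAGGCTTACGAGCAGTACTTC,True
AAACCTGAGCAGCGTA-1,True,True,TRA,TRAV8-6,TRAJ45,CAVSDLEPNSSASKIIF,,True
AAACCTGAGCAGCGTA-1,True,True,TRB,TRBV6-5,TRBJ1-1,CASSYSTGDNTEAFF,,True
AAACCTGAGCAGCGTA-1,True,True,TRB,TRBV20-1,TRBJ2-1,CSARDLTSGSYNEQFF,,True
AAACCTGCAGGCGATA-1,True,True,TRA,TRAV1-2,TRAJ12,CAVMDSSYKLIF,,True
AAACCTGCAGGCGATA-1,True,True,TRB,TRBV9,TRBJ2-5,None,,False
AAACCTGGTCCGAATT-1,True,True,IGH,IGHV3-23,IGHJ4,CAKDGYSSGWYFDYW,,True
AAACCTGGTCCGAATT-1,True,True,TRB,TRBV28,TRBJ1-4,CASSFQGNEKLFF,,True
AAACCTGTCAACGGGA-1,True,False,TRA,TRAV9-2,TRAJ23,CALSDYNQGGKLIF,,True
AAACCTGTCAACGGGA-1,True,True,TRB,TRBV19,TRBJ2-3,CASSIRSSYEQYF,,True
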