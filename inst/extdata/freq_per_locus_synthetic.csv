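mode,population,weight,locus,antigen,frequency
per_locus_antigen,pop1,1.0,A,A1,0.15
per_locus_antigen,pop1,1.0,A,A2,0.30
per_locus_antigen,pop1,1.0,A,A3,0.12
per_locus_antigen,pop1,1.0,A,A11,0.08
per_locus_antigen,pop1,1.0,A,A24,0.15
per_locus_antigen,pop1,1.0,A,A29,0.05
per_locus_antigen,pop1,1.0,A,A30,0.08
per_locus_antigen,pop1,1.0,A,A68,0.07
per_locus_antigen,pop1,1.0,B,B7,0.12
per_locus_antigen,pop1,1.0,B,B8,0.10
per_locus_antigen,pop1,1.0,B,B35,0.15
per_locus_antigen,pop1,1.0,B,B44,0.18
per_locus_antigen,pop1,1.0,B,B51,0.08
per_locus_antigen,pop1,1.0,B,B57,0.07
per_locus_antigen,pop1,1.0,B,B58,0.08
per_locus_antigen,pop1,1.0,B,B62,0.22
per_locus_antigen,pop1,1.0,C,Cw4,0.20
per_locus_antigen,pop1,1.0,C,Cw5,0.10
per_locus_antigen,pop1,1.0,C,Cw6,0.15
per_locus_antigen,pop1,1.0,C,Cw7,0.30
per_locus_antigen,pop1,1.0,C,Cw9,0.10
per_locus_antigen,pop1,1.0,C,Cw15,0.05
per_locus_antigen,pop1,1.0,C,Cw16,0.10
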