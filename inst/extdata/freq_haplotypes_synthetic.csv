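mode,population,weight,haplotype,frequency
haplotype,pop1,0.6,A1~B8~Cw7,0.15
haplotype,pop1,0.6,A2~B7~Cw7,0.20
haplotype,pop1,0.6,A2~B44~Cw5,0.15
haplotype,pop1,0.6,A3~B35~Cw4,0.10
haplotype,pop1,0.6,A11~B51~Cw15,0.10
haplotype,pop1,0.6,A24~B62~Cw9,0.10
haplotype,pop1,0.6,A29~B44~Cw16,0.08
haplotype,pop1,0.6,A30~B13~Cw6,0.12
haplotype,pop2,0.4,A2~B53~Cw4,0.18
haplotype,pop2,0.4,A23~B45~Cw16,0.12
haplotype,pop2,0.4,A30~B42~Cw17,0.15
haplotype,pop2,0.4,A68~B58~Cw6,0.15
haplotype,pop2,0.4,A1~B8~Cw7,0.05
haplotype,pop2,0.4,A3~B7~Cw7,0.10
haplotype,pop2,0.4,A33~B65~Cw8,0.15
haplotype,pop2,0.4,A74~B72~Cw7,0.10
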