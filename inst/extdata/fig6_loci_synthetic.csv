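symbol,species,trait,chrom,pos_cM,informative,position_status,paired_with,source
h8q24,human,colon,15,63,yes,synthetic,Sluc25,GWAS
h9q22.2-31.2,human,colon,13,36.7,yes,synthetic,Sluc23,linkage
h10p14,human,colon,2,7,yes,synthetic,Sluc16,GWAS
h3q21-24,human,colon,6,42,yes,synthetic,Pas1c,linkage
h14q22.2,human,colon,12,32.5,yes,synthetic,Sluc13,GWAS
h6q23-25,human,colon,10,1.5,yes,synthetic,Sluc29,linkage
h8q23.3,human,colon,15,57,yes,synthetic,Sluc25,GWAS
h16q22.1,human,colon,8,65,yes,synthetic,Sluc9,GWAS
h19q13.1,human,colon,7,1,yes,synthetic,Sluc30,GWAS
h15q13,human,colon,2,75,yes,synthetic,none,GWAS
h20p12.3,human,colon,2,105,yes,synthetic,none,GWAS
h18q21,human,colon,18,43,no,synthetic,none,GWAS
h11q23,human,colon,9,10,no,synthetic,none,GWAS
h5p15,human,lung,13,5,no,synthetic,none,GWAS
h6p21,human,lung,17,30,no,synthetic,none,GWAS
h15q25,human,lung,7,25,no,synthetic,none,GWAS
rCcr2,rat,colon,12,28,yes,synthetic,Sluc13,rat cross
rCcr3,rat,colon,18,24,yes,synthetic,Sluc14,rat cross
rCcr5,rat,colon,14,45,yes,synthetic,Sluc12,rat cross
rCcr7,rat,colon,13,41,yes,synthetic,Sluc23,rat cross
rCcs1,rat,colon,4,75,yes,synthetic,Sluc6,rat cross
rCcr6,rat,colon,19,45,yes,synthetic,none,rat cross
rCcr8,rat,colon,1,20,yes,synthetic,none,rat cross
rCcr1,rat,colon,11,10,no,synthetic,none,rat cross
rCcr4,rat,colon,10,45,no,synthetic,none,rat cross
rCcr9,rat,colon,16,40,no,synthetic,none,rat cross
Scc1,mouse,colon,2,18.5,yes,synthetic,Sluc31,CcS
Scc2,mouse,colon,2,32,yes,printed,Sluc2,CcS
Scc3,mouse,colon,1,101.5,yes,printed,Sluc5,CcS
Scc4,mouse,colon,17,11,yes,synthetic,Sluc32,CcS
Scc5,mouse,colon,18,25,yes,printed,Sluc14,CcS
Scc8,mouse,colon,8,4,yes,printed,Sluc20,CcS
Scc9,mouse,colon,10,63,yes,printed,Sluc22,CcS
Scc11,mouse,colon,4,57.4,yes,printed,Sluc21,CcS
Scc12,mouse,colon,7,63.5,yes,printed,Sluc19,CcS
Scc14,mouse,colon,10,2,yes,printed,Sluc29,CcS
Scc15,mouse,colon,11,33.9,yes,printed,Sluc4,CcS
Sluc31,mouse,lung,2,18,yes,synthetic,Scc1,F2 cross
Sluc32,mouse,lung,17,10,yes,synthetic,Scc4,F2 cross
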