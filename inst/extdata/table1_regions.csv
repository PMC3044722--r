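chrom,trait,region_start_cM,region_end_cM,locus_symbol,locus_cM,species,source,pair_id
1,colon,32.8,41,none,,mouse,CcS,p01
1,colon,81.6,127,Scc3,101.5,mouse,CcS,p02
2,colon,5,41.4,Scc2,32,mouse,CcS,p03
2,colon,45,95.5,none,,mouse,CcS,p04
3,colon,6.7,11.2,none,,mouse,CcS,p05
4,colon,20.8,40,none,,mouse,CcS,p06
4,colon,56.5,62.3,Scc11,57.4,mouse,CcS,p07
5,colon,61,78,none,,mouse,CcS,p08
6,colon,0,20.5,none,,mouse,CcS,p09
6,colon,42,61.4,none,,mouse,CcS,p10
6,colon,42,61.4,none,,mouse,CcS,p11
6,colon,62.5,75,none,,mouse,CcS,p12
7,colon,8,74,none,,mouse,CcS,p13
7,colon,8,74,Scc12,63.5,mouse,CcS,p14
8,colon,0,19.5,Scc8,4,mouse,CcS,p15
8,colon,41,67,none,,mouse,CcS,p16
10,colon,0,21,Scc14,2,mouse,CcS,p17
10,colon,49,77,Scc9,63,mouse,CcS,p18
11,colon,20,40,Scc15,33.9,mouse,CcS,p19
16,colon,0,28.2,none,,mouse,CcS,p20
18,colon,2,26,Scc5,25,mouse,CcS,p21
18,colon,31,37,none,,mouse,CcS,p22
19,colon,4.5,41,none,,mouse,CcS,p23
1,lung,0,59,none,,mouse,OcB,p01
1,lung,81.6,127,Sluc5,100,mouse,OcB,p02
2,lung,0,47.5,Sluc2,41,mouse,OcB,p03
2,lung,0,47.5,Sluc16,5,mouse,OcB,p03
2,lung,69,114,none,,mouse,OcB,p04
3,lung,0,45.2,none,,mouse,OcB,p05
4,lung,0,81,none,,mouse,OcB,p06
4,lung,0,81,Sluc21,62.3,mouse,OcB,p07
4,lung,0,81,Sluc6,67,mouse,OcB,p07
5,lung,64,92,none,,mouse,OcB,p08
6,lung,2.8,26.5,Sluc7,6,mouse,OcB,p09
6,lung,36.5,48.7,none,,mouse,OcB,p10
6,lung,58.6,63.6,Sluc3,61.2,mouse,OcB,p11
6,lung,67,75,none,,mouse,OcB,p12
7,lung,0,15,none,,mouse,OcB,p13
7,lung,28.7,74,Sluc19,63.5,mouse,OcB,p14
7,lung,28.7,74,Sluc8,72,mouse,OcB,p14
8,lung,0,31.5,Sluc20,10,mouse,OcB,p15
8,lung,53,73,Sluc9,59,mouse,OcB,p16
10,lung,0,36,Sluc29,4,mouse,OcB,p17
10,lung,51.5,77,Sluc22,61,mouse,OcB,p18
11,lung,27.9,40,Sluc4,40,mouse,OcB,p19
16,lung,0,27.6,none,,mouse,OcB,p20
18,lung,0,41,Sluc14,20,mouse,OcB,p21
18,lung,31,37,none,,mouse,OcB,p22
19,lung,4.5,53,none,,mouse,OcB,p23
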