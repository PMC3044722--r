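symbol,species,trait,chrom,pos_cM,position_status,source
Sluc1,mouse,lung,3,30,synthetic,OcB
Sluc2,mouse,lung,2,41,printed,OcB
Sluc3,mouse,lung,6,61.2,printed,OcB
Sluc4,mouse,lung,11,40,printed,OcB
Sluc5,mouse,lung,1,100,printed,OcB
Sluc6,mouse,lung,4,67,printed,OcB
Sluc7,mouse,lung,6,6,printed,OcB
Sluc8,mouse,lung,7,72,printed,OcB
Sluc9,mouse,lung,8,59,printed,OcB
Sluc10,mouse,lung,5,70,synthetic,OcB
Sluc11,mouse,lung,9,50,synthetic,OcB
Sluc12,mouse,lung,14,40,synthetic,OcB
Sluc13,mouse,lung,12,30,synthetic,OcB
Sluc14,mouse,lung,18,20,printed,OcB
Sluc15,mouse,lung,16,20,synthetic,OcB
Sluc16,mouse,lung,2,5,printed,OcB
Sluc17,mouse,lung,17,14,synthetic,OcB
Sluc18,mouse,lung,18,35,synthetic,OcB
Sluc19,mouse,lung,7,63.5,printed,OcB
Sluc20,mouse,lung,8,10,printed,OcB
Sluc21,mouse,lung,4,62.3,printed,OcB
Sluc22,mouse,lung,10,61,printed,OcB
Sluc23,mouse,lung,13,35,synthetic,OcB
Sluc24,mouse,lung,19,30,synthetic,OcB
Sluc25,mouse,lung,15,62,synthetic,OcB
Sluc26,mouse,lung,1,40,synthetic,OcB
Sluc27,mouse,lung,2,90,synthetic,OcB
Sluc28,mouse,lung,12,55,synthetic,OcB
Sluc29,mouse,lung,10,4,printed,OcB
Sluc30,mouse,lung,7,8,synthetic,OcB
Pas1c,mouse,lung,6,40,synthetic,other
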