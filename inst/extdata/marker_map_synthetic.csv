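marker,chrom,cM
D1Mit291,1,95
D1Mit155,1,103
D2Mit99,2,18
D2Mit156,2,63
D2Nds3,2,70
D4Mit53,4,28
D4Mit15,4,35
D5Mit68,5,50
D6Mit177,6,40
D7Mit105,7,30
D8Mit17,8,15
D8Mit36,8,33
D9Mit254,9,45
D10Mit28,10,5
D10Mit2,10,60
D11Mit316,11,35
D14Mit11,14,25
D15Mit16,15,45
D17Mit72,17,10
D17Mit123,17,18
D18Mit17,18,15
D18Mit124,18,37
D19Mit6,19,25
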