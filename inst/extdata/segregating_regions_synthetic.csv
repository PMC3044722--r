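chrom,start,end
1,85,112
2,12,26
2,58,66
2,67,76
4,22,34
4,34.5,42
5,40,60
6,33,48
7,20,42
8,8,22
8,26,40
9,35,55
10,0,13
10,50,70
11,25,45
14,15,35
15,35,55
17,4,24
18,8,22
18,28,44
19,15,35
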