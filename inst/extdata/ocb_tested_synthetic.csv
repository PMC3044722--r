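chrom,start,end
1,0,59
1,81.6,127
2,0,47.5
2,69,114
3,0,45.2
4,0,81
5,64,92
6,2.8,26.5
6,36.5,48.7
6,58.6,63.6
6,67,75
7,0,15
7,28.7,74
8,0,31.5
8,53,73
9,40,60
10,0,36
10,51.5,77
11,27.9,40
12,20,40
12,45,65
13,25,45
14,30,50
15,50,70
16,0,27.6
17,5,25
18,0,41
19,4.5,53
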