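picture_id,tp,fp,fn,nfp
1,70,2,8,78
2,44,3,9,53
3,62,3,6,68
4,53,4,5,58
5,20,2,4,24
6,41,3,9,50
7,67,3,5,72
8,83,5,8,91
9,86,7,10,96
10,77,6,4,81
11,80,7,6,86
12,61,3,6,67
13,75,4,1,76
14,73,5,8,81
15,30,6,4,34
16,38,5,7,45
17,56,3,8,64
18,53,7,3,56
19,67,8,9,76
20,91,2,7,98
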