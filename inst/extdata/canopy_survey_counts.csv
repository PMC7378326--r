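tree_id,count_top,count_middle,count_underside
1,88,95,92
5,85,101,99
9,66,77,95
14,83,68,77
17,56,75,82
24,51,93,82
25,86,87,70
27,77,107,124
32,53,78,125
33,88,117,64
34,56,89,107
43,35,202,82
48,80,117,70
50,90,95,72
51,63,44,68
56,77,84,78
57,48,128,97
59,69,88,98
62,52,110,108
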