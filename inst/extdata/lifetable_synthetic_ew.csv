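age,sex,qx_noncvd
80,M,0.044003
81,M,0.049056
82,M,0.054672
83,M,0.06091
84,M,0.067834
85,M,0.075513
86,M,0.084021
87,M,0.093439
88,M,0.103851
89,M,0.115348
90,M,0.128024
91,M,0.141977
92,M,0.15731
93,M,0.174125
94,M,0.192522
95,M,0.212602
96,M,0.234455
97,M,0.258165
98,M,0.283799
99,M,0.311404
100,M,0.341003
101,M,0.372584
102,M,0.406096
103,M,0.44144
104,M,0.478463
105,M,0.516949
106,M,0.556615
107,M,0.597109
108,M,0.638011
109,M,0.678835
110,M,0.719042
80,F,0.031627
81,F,0.035771
82,F,0.040447
83,F,0.045719
84,F,0.05166
85,F,0.058349
86,F,0.065874
87,F,0.07433
88,F,0.083823
89,F,0.094464
90,F,0.106376
91,F,0.119688
92,F,0.134537
93,F,0.151065
94,F,0.169418
95,F,0.18974
96,F,0.212174
97,F,0.236851
98,F,0.263889
99,F,0.293378
100,F,0.325376
101,F,0.359897
102,F,0.396893
103,F,0.436248
104,F,0.477759
105,F,0.521126
106,F,0.565942
107,F,0.61169
108,F,0.657741
109,F,0.70337
110,F,0.747778
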