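"age","q_annual"
60,0.00647892069655231
61,0.00705168032971026
62,0.00767487809091105
63,0.00835291941452587
64,0.00909058781374428
65,0.00989307608187995
66,0.0107660198347882
67,0.0117155335249232
68,0.0127482490554044
69,0.0138713571177232
70,0.0150926513687849
71,0.0164205755510977
72,0.0178642736432194
73,0.0194336431050244
74,0.0211393912527469
75,0.0229930947606987
76,0.0250072622383982
77,0.0271953997717211
78,0.0295720792424032
79,0.0321530091493371
80,0.0349551075447867
81,0.0379965765657363
82,0.0412969778815621
83,0.0448773081901582
84,0.0487600736712914
85,0.0529693620437008
86,0.0575309105664522
87,0.0624721679702674
88,0.0678223478959907
89,0.0736124709502444
90,0.0798753919584838
91,0.0866458083999121
92,0.0939602453454788
93,0.101857011490284
94,0.110376120079316
95,0.119559167679298
96,0.12944916286448
97,0.140090295983258
98,0.15152764028868
99,0.16380677389499
100,0.176973311325752
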