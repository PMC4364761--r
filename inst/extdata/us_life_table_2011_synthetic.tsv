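# Synthetic stand-in for the US 2011 period life table (total population).
# Annual all-cause mortality probability qx by single year of age, 45-94.
# Log-linear interpolation between approximate NVSS-2011 anchor values;
# NOT the official CDC table. Swappable via read_life_table().
age	qx
45	0.00341
46	0.00366642
47	0.00394213
48	0.00423857
49	0.0045573
50	0.0049
51	0.00529057
52	0.00571228
53	0.00616759
54	0.0066592
55	0.00719
56	0.00770025
57	0.00824672
58	0.00883196
59	0.00945874
60	0.01013
61	0.0108652
62	0.0116538
63	0.0124997
64	0.0134069
65	0.01438
66	0.0155203
67	0.0167509
68	0.0180792
69	0.0195127
70	0.02106
71	0.0229336
72	0.0249739
73	0.0271958
74	0.0296153
75	0.03225
76	0.0354382
77	0.0389415
78	0.0427912
79	0.0470215
80	0.05167
81	0.0571725
82	0.0632609
83	0.0699977
84	0.0774519
85	0.0857
86	0.0951323
87	0.105603
88	0.117226
89	0.130128
90	0.14445
91	0.158423
92	0.173747
93	0.190553
94	0.208985
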