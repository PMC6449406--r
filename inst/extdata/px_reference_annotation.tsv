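column	element	anchor
1	beta1	
2	beta1	
3	beta1	
4	beta1	
5	beta1	
6	beta1	
7	beta1	
8	beta1	
9	beta1	
10	beta1	
11	other	
12	other	
13	other	
14	other	
15	other	
16	beta2	
17	beta2	
18	beta2	
19	beta2	
20	beta2	
21	beta2	
22	beta2	
23	beta2	
24	beta2	
25	beta2	
26	other	
27	other	
28	other	
29	other	
30	other	
31	beta3	
32	beta3	
33	beta3	
34	beta3	
35	beta3	
36	beta3	
37	beta3	
38	beta3	
39	beta3	
40	beta3	
41	beta3	junction_arg
42	beta3	junction_tyr
43	alpha1	alpha1_first
44	alpha1	
45	alpha1	
46	alpha1	
47	alpha1	
48	alpha1	
49	alpha1	
50	alpha1	
51	alpha1	
52	alpha1	
53	alpha1	
54	alpha1	
55	alpha1	
56	alpha1	
57	ppk_loop	
58	ppk_loop	
59	ppk_loop	
60	ppk_loop	
61	ppk_loop	
62	ppk_loop	
63	ppk_loop	ppk_lys
64	ppk_loop	
65	ppk_loop	
66	ppk_loop	
67	ppk_loop	
68	ppk_loop	
69	ppk_loop	
70	ppk_loop	
71	ppk_loop	
72	ppk_loop	
73	ppk_loop	
74	ppk_loop	
75	ppk_loop	
76	alpha2	
77	alpha2	
78	alpha2	
79	alpha2	
80	alpha2	
81	alpha2	
82	alpha2	
83	alpha2	
84	alpha2	
85	alpha2	alpha2_arg
86	alpha2	
87	alpha2	
88	alpha2	
89	alpha2	
90	alpha2	
91	alpha2	
92	alpha2	
93	alpha2	
94	alpha2	
95	alpha2	
96	alpha3	
97	alpha3	
98	alpha3	
99	alpha3	
100	alpha3	
101	alpha3	
102	alpha3	
103	alpha3	
104	alpha3	
105	alpha3	
106	alpha3	
107	alpha3	
108	alpha3	
109	alpha3	
110	alpha3	
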