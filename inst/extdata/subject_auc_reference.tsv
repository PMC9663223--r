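subject	auc
1	0.99
2	0.96
3	0.92
4	0.95
5	1.00
6	0.93
7	0.96
8	0.94
9	0.96
10	0.99
11	0.99
12	0.97
13	0.95
14	0.99
15	0.99
16	0.95
17	0.85
18	0.99
19	1.00
20	0.97
21	0.97
22	1.00
23	0.99
24	1.00
25	0.98
26	0.97
27	0.98
28	0.97
29	1.00
30	1.00
31	1.00
32	0.99
33	1.00
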