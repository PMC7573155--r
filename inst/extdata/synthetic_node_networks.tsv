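node	network
1	visual
2	somato-motor
3	dorsal attention
4	ventral attention
5	fronto-temporal
6	fronto-parietal
7	default mode
8	basal ganglia
9	cerebellum
10	visual
11	somato-motor
12	dorsal attention
13	ventral attention
14	fronto-temporal
15	fronto-parietal
16	default mode
17	basal ganglia
18	cerebellum
19	visual
20	somato-motor
21	dorsal attention
22	ventral attention
23	fronto-temporal
24	fronto-parietal
25	default mode
26	basal ganglia
27	cerebellum
28	visual
29	somato-motor
30	dorsal attention
31	ventral attention
32	fronto-temporal
33	fronto-parietal
34	default mode
35	basal ganglia
36	cerebellum
37	visual
38	somato-motor
39	dorsal attention
40	ventral attention
41	fronto-temporal
42	fronto-parietal
43	default mode
44	basal ganglia
45	cerebellum
46	visual
47	somato-motor
48	dorsal attention
49	ventral attention
50	fronto-temporal
51	fronto-parietal
52	default mode
53	basal ganglia
54	cerebellum
55	visual
56	somato-motor
57	dorsal attention
58	ventral attention
59	fronto-temporal
60	fronto-parietal
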