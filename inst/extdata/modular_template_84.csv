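node,label,module
1,lh.frontal.01,1
2,lh.frontal.02,1
3,lh.frontal.03,1
4,lh.frontal.04,1
5,lh.frontal.05,1
6,lh.frontal.06,1
7,lh.frontal.07,1
8,rh.frontal.01,1
9,rh.frontal.02,1
10,rh.frontal.03,1
11,rh.frontal.04,1
12,rh.frontal.05,1
13,rh.frontal.06,1
14,rh.frontal.07,1
15,lh.parietal.01,2
16,lh.parietal.02,2
17,lh.parietal.03,2
18,lh.parietal.04,2
19,lh.parietal.05,2
20,lh.parietal.06,2
21,lh.parietal.07,2
22,rh.parietal.01,2
23,rh.parietal.02,2
24,rh.parietal.03,2
25,rh.parietal.04,2
26,rh.parietal.05,2
27,rh.parietal.06,2
28,rh.parietal.07,2
29,lh.temporal.01,3
30,lh.temporal.02,3
31,lh.temporal.03,3
32,lh.temporal.04,3
33,lh.temporal.05,3
34,lh.temporal.06,3
35,lh.temporal.07,3
36,rh.temporal.01,3
37,rh.temporal.02,3
38,rh.temporal.03,3
39,rh.temporal.04,3
40,rh.temporal.05,3
41,rh.temporal.06,3
42,rh.temporal.07,3
43,lh.occipital.01,4
44,lh.occipital.02,4
45,lh.occipital.03,4
46,lh.occipital.04,4
47,lh.occipital.05,4
48,lh.occipital.06,4
49,lh.occipital.07,4
50,rh.occipital.01,4
51,rh.occipital.02,4
52,rh.occipital.03,4
53,rh.occipital.04,4
54,rh.occipital.05,4
55,rh.occipital.06,4
56,rh.occipital.07,4
57,lh.subcortical.01,5
58,lh.subcortical.02,5
59,lh.subcortical.03,5
60,lh.subcortical.04,5
61,lh.subcortical.05,5
62,lh.subcortical.06,5
63,lh.subcortical.07,5
64,rh.subcortical.01,5
65,rh.subcortical.02,5
66,rh.subcortical.03,5
67,rh.subcortical.04,5
68,rh.subcortical.05,5
69,rh.subcortical.06,5
70,rh.subcortical.07,5
71,lh.cingulate.01,6
72,lh.cingulate.02,6
73,lh.cingulate.03,6
74,lh.cingulate.04,6
75,lh.cingulate.05,6
76,lh.cingulate.06,6
77,lh.cingulate.07,6
78,rh.cingulate.01,6
79,rh.cingulate.02,6
80,rh.cingulate.03,6
81,rh.cingulate.04,6
82,rh.cingulate.05,6
83,rh.cingulate.06,6
84,rh.cingulate.07,6
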