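sample_id,measured,estimated,relative_error_printed
1,0.393,0.433,0.103
2,0.244,0.215,0.119
3,0.328,0.319,0.027
4,0.122,0.096,0.218
5,0.259,0.272,0.049
6,0.486,0.562,0.156
7,0.319,0.290,0.090
8,0.165,0.174,0.057
9,0.173,0.201,0.162
10,0.298,0.269,0.097
11,0.389,0.416,0.069
12,0.235,0.284,0.208
13,0.225,0.222,0.012
14,0.102,0.131,0.282
15,0.105,0.141,0.340
16,0.152,0.163,0.077
17,0.403,0.340,0.157
18,0.144,0.154,0.071
19,0.108,0.124,0.150
20,0.273,0.267,0.025
21,0.388,0.404,0.042
22,0.371,0.387,0.045
23,0.456,0.480,0.052
24,0.264,0.247,0.064
25,0.348,0.330,0.053
26,0.257,0.240,0.065
27,0.170,0.136,0.198
28,0.184,0.149,0.191
29,0.353,0.337,0.044
30,0.351,0.343,0.023
31,0.296,0.255,0.138
32,0.356,0.342,0.039
33,0.214,0.233,0.088
34,0.215,0.277,0.286
35,0.172,0.150,0.132
36,0.163,0.146,0.103
37,0.067,0.077,0.148
38,0.075,0.077,0.017
39,0.117,0.127,0.082
40,0.253,0.242,0.047
41,0.381,0.418,0.097
42,0.145,0.125,0.137
43,0.268,0.259,0.036
44,0.272,0.247,0.091
45,0.060,0.046,0.231
46,0.298,0.323,0.087
47,0.192,0.168,0.126
48,0.209,0.209,0.001
49,0.361,0.343,0.049
50,0.112,0.150,0.344
51,0.233,0.193,0.171
52,0.226,0.215,0.048
53,0.253,0.281,0.110
54,0.299,0.271,0.093
55,0.056,0.071,0.262
56,0.138,0.168,0.218
57,0.141,0.167,0.188
58,0.109,0.106,0.035
59,0.201,0.207,0.028
60,0.385,0.425,0.105
61,0.314,0.289,0.079
62,0.120,0.130,0.089
63,0.227,0.201,0.113
64,0.125,0.120,0.044
65,0.416,0.451,0.084
66,0.160,0.195,0.219
67,0.281,0.278,0.011
68,0.162,0.186,0.149
69,0.322,0.277,0.141
70,0.195,0.231,0.184
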