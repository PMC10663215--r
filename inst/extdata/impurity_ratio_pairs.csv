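sample_id,measured,estimated,relative_error_printed
1,0.473,0.499,0.055
2,0.237,0.254,0.071
3,0.423,0.424,0.004
4,0.292,0.298,0.021
5,0.303,0.263,0.133
6,0.602,0.570,0.053
7,0.445,0.445,0.002
8,0.372,0.341,0.082
9,0.393,0.352,0.104
10,0.294,0.280,0.048
11,0.529,0.554,0.046
12,0.277,0.272,0.018
13,0.378,0.388,0.028
14,0.206,0.199,0.034
15,0.332,0.314,0.055
16,0.240,0.217,0.098
17,0.482,0.452,0.062
18,0.277,0.298,0.073
19,0.331,0.317,0.043
20,0.274,0.265,0.034
21,0.358,0.322,0.102
22,0.491,0.470,0.042
23,0.417,0.439,0.054
24,0.286,0.318,0.110
25,0.273,0.241,0.119
26,0.316,0.337,0.066
27,0.267,0.265,0.006
28,0.251,0.272,0.082
29,0.208,0.249,0.196
30,0.375,0.334,0.109
31,0.296,0.347,0.173
32,0.229,0.290,0.265
33,0.283,0.279,0.014
34,0.357,0.332,0.072
35,0.350,0.342,0.024
36,0.328,0.319,0.026
37,0.313,0.322,0.032
38,0.091,0.104,0.142
39,0.217,0.240,0.103
40,0.380,0.381,0.001
41,0.241,0.240,0.005
42,0.369,0.369,0.000
43,0.292,0.282,0.035
44,0.328,0.337,0.026
45,0.146,0.167,0.148
46,0.274,0.316,0.156
47,0.310,0.273,0.118
48,0.410,0.382,0.068
49,0.254,0.269,0.063
50,0.320,0.319,0.004
51,0.343,0.386,0.124
52,0.328,0.325,0.009
53,0.385,0.355,0.077
54,0.211,0.232,0.102
55,0.228,0.248,0.088
56,0.420,0.389,0.073
57,0.268,0.267,0.007
58,0.209,0.200,0.043
59,0.239,0.245,0.023
60,0.427,0.421,0.014
61,0.332,0.320,0.036
62,0.319,0.315,0.011
63,0.253,0.239,0.054
64,0.313,0.339,0.082
65,0.500,0.483,0.034
66,0.418,0.378,0.095
67,0.297,0.320,0.077
68,0.299,0.337,0.128
69,0.475,0.465,0.021
70,0.301,0.302,0.002
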