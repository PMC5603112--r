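group,density,E1,E2,E3,nu12,nu23,nu31,G12,G23,G31
1,0.997,1.151,1.151,1.894,0.4,0.25,0.25,0.053,0.066,0.061
2,0.998,1.153,1.153,1.897,0.4,0.25,0.25,0.053,0.066,0.061
3,0.999,1.154,1.154,1.9,0.4,0.25,0.25,0.053,0.066,0.061
4,1,1.156,1.156,1.903,0.4,0.25,0.25,0.053,0.066,0.061
5,1.001,1.158,1.158,1.906,0.4,0.25,0.25,0.053,0.066,0.061
6,1.002,1.16,1.16,1.909,0.4,0.25,0.25,0.053,0.066,0.061
7,1.002,1.162,1.162,1.912,0.4,0.25,0.25,0.053,0.066,0.061
8,1.003,1.164,1.164,1.915,0.4,0.25,0.25,0.053,0.067,0.062
9,1.004,1.166,1.166,1.918,0.4,0.25,0.25,0.054,0.067,0.062
10,1.005,1.168,1.168,1.921,0.4,0.25,0.25,0.054,0.067,0.062
11,1.006,1.17,1.17,1.923,0.4,0.25,0.25,0.054,0.067,0.062
12,1.007,1.172,1.172,1.926,0.4,0.25,0.25,0.054,0.067,0.062
13,1.008,1.174,1.174,1.929,0.4,0.25,0.25,0.054,0.067,0.062
14,1.009,1.176,1.176,1.932,0.4,0.25,0.25,0.054,0.067,0.062
15,1.01,1.178,1.178,1.935,0.4,0.25,0.25,0.054,0.067,0.062
16,1.011,1.18,1.18,1.938,0.4,0.25,0.25,0.054,0.068,0.063
17,1.012,1.181,1.181,1.941,0.4,0.25,0.25,0.054,0.068,0.063
18,1.013,1.183,1.183,1.944,0.4,0.25,0.25,0.054,0.068,0.063
19,1.014,1.185,1.185,1.947,0.4,0.25,0.25,0.055,0.068,0.063
20,1.015,1.187,1.187,1.95,0.4,0.25,0.25,0.055,0.068,0.063
21,1.016,1.189,1.189,1.953,0.4,0.25,0.25,0.055,0.068,0.063
22,1.016,1.191,1.191,1.956,0.4,0.25,0.25,0.055,0.068,0.063
23,1.017,1.193,1.193,1.959,0.4,0.25,0.25,0.055,0.068,0.063
24,1.018,1.195,1.195,1.962,0.4,0.25,0.25,0.055,0.069,0.063
25,1.019,1.197,1.197,1.965,0.4,0.25,0.25,0.055,0.069,0.064
26,1.02,1.199,1.199,1.968,0.4,0.25,0.25,0.055,0.069,0.064
27,1.021,1.201,1.201,1.971,0.4,0.25,0.25,0.055,0.069,0.064
28,1.022,1.203,1.203,1.973,0.4,0.25,0.25,0.055,0.069,0.064
29,1.023,1.205,1.205,1.976,0.4,0.25,0.25,0.056,0.069,0.064
30,1.024,1.207,1.207,1.979,0.4,0.25,0.25,0.056,0.069,0.064
31,1.025,1.209,1.209,1.982,0.4,0.25,0.25,0.056,0.069,0.064
32,1.026,1.211,1.211,1.985,0.4,0.25,0.25,0.056,0.07,0.064
33,1.027,1.213,1.213,1.988,0.4,0.25,0.25,0.056,0.07,0.065
34,1.028,1.215,1.215,1.991,0.4,0.25,0.25,0.056,0.07,0.065
35,1.029,1.217,1.217,1.994,0.4,0.25,0.25,0.056,0.07,0.065
36,1.03,1.219,1.219,1.997,0.4,0.25,0.25,0.056,0.07,0.065
37,1.03,1.221,1.221,2,0.4,0.25,0.25,0.056,0.07,0.065
38,1.031,1.223,1.223,2.003,0.4,0.25,0.25,0.056,0.07,0.065
39,1.032,1.224,1.224,2.006,0.4,0.25,0.25,0.057,0.07,0.065
40,1.033,1.226,1.226,2.009,0.4,0.25,0.25,0.057,0.071,0.065
41,1.034,1.228,1.228,2.012,0.4,0.25,0.25,0.057,0.071,0.065
42,1.035,1.23,1.23,2.015,0.4,0.25,0.25,0.057,0.071,0.066
43,1.036,1.232,1.232,2.018,0.4,0.25,0.25,0.057,0.071,0.066
44,1.037,1.234,1.234,2.021,0.4,0.25,0.25,0.057,0.071,0.066
45,1.038,12.363,12.363,20.24,0.4,0.25,0.25,5.367,6.683,6.185
46,1.039,12.383,12.383,20.269,0.4,0.25,0.25,5.377,6.695,6.196
47,1.04,12.403,12.403,20.299,0.4,0.25,0.25,5.386,6.707,6.207
48,1.041,12.423,12.423,20.329,0.4,0.25,0.25,5.396,6.719,6.218
49,1.042,12.442,12.442,20.359,0.4,0.25,0.25,5.406,6.731,6.229
50,1.043,12.462,12.462,20.389,0.4,0.25,0.25,5.415,6.743,6.24
51,1.044,12.482,12.482,20.419,0.4,0.25,0.25,5.425,6.755,6.252
52,1.044,12.502,12.502,20.449,0.4,0.25,0.25,5.435,6.767,6.263
53,1.045,12.522,12.522,20.479,0.4,0.25,0.25,5.444,6.779,6.274
54,1.046,12.542,12.542,20.509,0.4,0.25,0.25,5.454,6.791,6.285
55,1.047,12.562,12.562,20.539,0.4,0.25,0.25,5.464,6.804,6.296
56,1.048,12.582,12.582,20.569,0.4,0.25,0.25,5.474,6.816,6.308
57,1.049,12.602,12.602,20.599,0.4,0.25,0.25,5.483,6.828,6.319
58,1.05,12.622,12.622,20.629,0.4,0.25,0.25,5.493,6.84,6.33
59,1.051,12.642,12.642,20.659,0.4,0.25,0.25,5.503,6.852,6.341
60,1.052,12.662,12.662,20.689,0.4,0.25,0.25,5.513,6.864,6.353
61,1.053,12.682,12.682,20.719,0.4,0.25,0.25,5.522,6.876,6.364
62,1.054,12.702,12.702,20.749,0.4,0.25,0.25,5.532,6.889,6.375
63,1.055,12.722,12.722,20.779,0.4,0.25,0.25,5.542,6.901,6.386
64,1.056,12.742,12.742,20.81,0.4,0.25,0.25,5.552,6.913,6.398
65,1.057,12.762,12.762,20.84,0.4,0.25,0.25,5.562,6.925,6.409
66,1.058,12.782,12.782,20.87,0.4,0.25,0.25,5.572,6.938,6.42
67,1.058,12.802,12.802,20.9,0.4,0.25,0.25,5.581,6.95,6.432
68,1.059,12.822,12.822,20.93,0.4,0.25,0.25,5.591,6.962,6.443
69,1.06,12.842,12.842,20.961,0.4,0.25,0.25,5.601,6.974,6.454
70,1.061,12.862,12.862,20.991,0.4,0.25,0.25,5.611,6.987,6.466
71,1.062,12.882,12.882,21.021,0.4,0.25,0.25,5.621,6.999,6.477
72,1.063,12.902,12.902,21.051,0.4,0.25,0.25,5.631,7.011,6.489
73,1.064,12.923,12.923,21.082,0.4,0.25,0.25,5.641,7.024,6.5
74,1.065,12.943,12.943,21.112,0.4,0.25,0.25,5.65,7.036,6.511
75,1.066,12.963,12.963,21.142,0.4,0.25,0.25,5.66,7.048,6.523
76,1.067,12.983,12.983,21.173,0.4,0.25,0.25,5.67,7.061,6.534
77,1.068,13.003,13.003,21.203,0.4,0.25,0.25,5.68,7.073,6.546
78,1.069,13.024,13.024,21.234,0.4,0.25,0.25,5.69,7.085,6.557
79,1.07,13.044,13.044,21.264,0.4,0.25,0.25,5.7,7.098,6.569
80,1.071,13.064,13.064,21.294,0.4,0.25,0.25,5.71,7.11,6.58
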