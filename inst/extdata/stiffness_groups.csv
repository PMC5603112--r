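group,density,C11,C22,C33,C12,C13,C23,C44,C55,C66
1,0.997,1.423,1.483,2.187,0.534,0.297,0.237,0.066,0.061,0.053
2,0.998,1.426,1.541,2.455,0.535,0.297,0.238,0.066,0.061,0.053
3,0.999,1.428,1.546,2.467,0.536,0.298,0.238,0.066,0.061,0.053
4,1,1.431,1.551,2.479,0.536,0.298,0.238,0.066,0.061,0.053
5,1.001,1.433,1.556,2.491,0.537,0.299,0.239,0.066,0.061,0.053
6,1.002,1.435,1.561,2.503,0.538,0.299,0.239,0.066,0.061,0.053
7,1.002,1.438,1.566,2.516,0.539,0.3,0.24,0.066,0.061,0.053
8,1.003,1.44,1.572,2.528,0.54,0.3,0.24,0.067,0.062,0.053
9,1.004,1.442,1.577,2.54,0.541,0.301,0.24,0.067,0.062,0.054
10,1.005,1.445,1.582,2.552,0.542,0.301,0.241,0.067,0.062,0.054
11,1.006,1.447,1.587,2.565,0.543,0.302,0.241,0.067,0.062,0.054
12,1.007,1.45,1.593,2.577,0.544,0.302,0.242,0.067,0.062,0.054
13,1.008,1.452,1.598,2.589,0.545,0.303,0.242,0.067,0.062,0.054
14,1.009,1.454,1.603,2.602,0.545,0.303,0.242,0.067,0.062,0.054
15,1.01,1.457,1.608,2.614,0.546,0.304,0.243,0.067,0.062,0.054
16,1.011,1.459,1.614,2.627,0.547,0.304,0.243,0.068,0.063,0.054
17,1.012,1.462,1.619,2.64,0.548,0.305,0.244,0.068,0.063,0.054
18,1.013,1.464,1.624,2.652,0.549,0.305,0.244,0.068,0.063,0.054
19,1.014,1.466,1.63,2.665,0.55,0.306,0.244,0.068,0.063,0.055
20,1.015,1.469,1.635,2.678,0.551,0.306,0.245,0.068,0.063,0.055
21,1.016,1.471,1.64,2.691,0.552,0.307,0.245,0.068,0.063,0.055
22,1.016,1.474,1.646,2.704,0.553,0.307,0.246,0.068,0.063,0.055
23,1.017,1.476,1.651,2.717,0.554,0.308,0.246,0.068,0.063,0.055
24,1.018,1.478,1.656,2.729,0.554,0.308,0.246,0.069,0.063,0.055
25,1.019,1.481,1.662,2.743,0.555,0.309,0.247,0.069,0.064,0.055
26,1.02,1.483,1.667,2.756,0.556,0.309,0.247,0.069,0.064,0.055
27,1.021,1.486,1.673,2.769,0.557,0.31,0.248,0.069,0.064,0.055
28,1.022,1.488,1.678,2.782,0.558,0.31,0.248,0.069,0.064,0.055
29,1.023,1.491,1.684,2.795,0.559,0.311,0.248,0.069,0.064,0.056
30,1.024,1.493,1.689,2.808,0.56,0.311,0.249,0.069,0.064,0.056
31,1.025,1.495,1.695,2.822,0.561,0.312,0.249,0.069,0.064,0.056
32,1.026,1.498,1.7,2.835,0.562,0.312,0.25,0.07,0.064,0.056
33,1.027,1.5,1.706,2.849,0.563,0.313,0.25,0.07,0.065,0.056
34,1.028,1.503,1.711,2.862,0.563,0.313,0.25,0.07,0.065,0.056
35,1.029,1.505,1.717,2.876,0.564,0.314,0.251,0.07,0.065,0.056
36,1.03,1.508,1.722,2.889,0.565,0.314,0.251,0.07,0.065,0.056
37,1.03,1.51,1.728,2.903,0.566,0.315,0.252,0.07,0.065,0.056
38,1.031,1.512,1.733,2.917,0.567,0.315,0.252,0.07,0.065,0.056
39,1.032,1.515,1.739,2.93,0.568,0.316,0.252,0.07,0.065,0.057
40,1.033,1.517,1.745,2.944,0.569,0.316,0.253,0.071,0.065,0.057
41,1.034,1.52,1.75,2.958,0.57,0.317,0.253,0.071,0.065,0.057
42,1.035,1.522,1.756,2.972,0.571,0.317,0.254,0.071,0.066,0.057
43,1.036,1.525,1.761,2.986,0.572,0.318,0.254,0.071,0.066,0.057
44,1.037,1.527,1.767,3,0.573,0.318,0.255,0.071,0.066,0.057
45,1.038,15.295,15.932,23.369,5.736,3.186,2.549,6.683,6.185,5.367
46,1.039,15.319,15.958,23.404,5.745,3.192,2.553,6.695,6.196,5.377
47,1.04,15.344,15.983,23.438,5.754,3.197,2.557,6.707,6.207,5.386
48,1.041,15.368,16.009,23.473,5.763,3.202,2.561,6.719,6.218,5.396
49,1.042,15.393,16.034,23.507,5.772,3.207,2.565,6.731,6.229,5.406
50,1.043,15.417,16.06,23.542,5.781,3.212,2.57,6.743,6.24,5.415
51,1.044,15.442,16.085,23.576,5.791,3.217,2.574,6.755,6.252,5.425
52,1.044,15.466,16.111,23.611,5.8,3.222,2.578,6.767,6.263,5.435
53,1.045,15.491,16.137,23.646,5.809,3.227,2.582,6.779,6.274,5.444
54,1.046,15.516,16.162,23.68,5.818,3.232,2.586,6.791,6.285,5.454
55,1.047,15.54,16.188,23.715,5.828,3.238,2.59,6.804,6.296,5.464
56,1.048,15.565,16.214,23.75,5.837,3.243,2.594,6.816,6.308,5.474
57,1.049,15.59,16.239,23.784,5.846,3.248,2.598,6.828,6.319,5.483
58,1.05,15.614,16.265,23.819,5.855,3.253,2.602,6.84,6.33,5.493
59,1.051,15.639,16.291,23.854,5.865,3.258,2.607,6.852,6.341,5.503
60,1.052,15.664,16.316,23.888,5.874,3.263,2.611,6.864,6.353,5.513
61,1.053,15.689,16.342,23.923,5.883,3.268,2.615,6.876,6.364,5.522
62,1.054,15.713,16.368,23.958,5.892,3.274,2.619,6.889,6.375,5.532
63,1.055,15.738,16.394,23.993,5.902,3.279,2.623,6.901,6.386,5.542
64,1.056,15.763,16.42,24.028,5.911,3.284,2.627,6.913,6.398,5.552
65,1.057,15.788,16.445,24.062,5.92,3.289,2.631,6.925,6.409,5.562
66,1.058,15.812,16.471,24.097,5.93,3.294,2.635,6.938,6.42,5.572
67,1.058,15.837,16.497,24.132,5.939,3.299,2.64,6.95,6.432,5.581
68,1.059,15.862,16.523,24.167,5.948,3.305,2.644,6.962,6.443,5.591
69,1.06,15.887,16.549,24.202,5.958,3.31,2.648,6.974,6.454,5.601
70,1.061,15.912,16.575,24.237,5.967,3.315,2.652,6.987,6.466,5.611
71,1.062,15.937,16.601,24.272,5.976,3.32,2.656,6.999,6.477,5.621
72,1.063,15.962,16.627,24.307,5.986,3.325,2.66,7.011,6.489,5.631
73,1.064,15.987,16.653,24.342,5.995,3.331,2.664,7.024,6.5,5.641
74,1.065,16.012,16.679,24.377,6.004,3.336,2.669,7.036,6.511,5.65
75,1.066,16.037,16.705,24.412,6.014,3.341,2.673,7.048,6.523,5.66
76,1.067,16.062,16.731,24.447,6.023,3.346,2.677,7.061,6.534,5.67
77,1.068,16.087,16.757,24.482,6.033,3.351,2.681,7.073,6.546,5.68
78,1.069,16.112,16.783,24.517,6.042,3.357,2.685,7.085,6.557,5.69
79,1.07,16.137,16.809,24.552,6.051,3.362,2.689,7.098,6.569,5.7
80,1.071,16.162,16.835,24.587,6.061,3.367,2.694,7.11,6.58,5.71
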