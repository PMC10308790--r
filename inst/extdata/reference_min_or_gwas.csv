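n_cases,j,maf_0.01,maf_0.05,maf_0.1,maf_0.2,maf_0.5
2500,1,2.74,1.68,1.48,1.35,1.29
2500,4,2.42,1.54,1.38,1.28,1.22
2500,10,2.35,1.51,1.35,1.26,1.21
2500,50,2.31,1.49,1.34,1.25,1.20
5000,1,2.12,1.46,1.33,1.24,1.20
5000,4,1.91,1.36,1.26,1.19,1.15
5000,10,1.86,1.34,1.24,1.18,1.14
5000,50,1.83,1.33,1.23,1.17,1.14
10000,1,1.74,1.31,1.22,1.17,1.13
10000,4,1.60,1.25,1.18,1.13,1.105
10000,10,1.57,1.23,1.17,1.12,1.098
10000,50,1.55,1.23,1.16,1.12,1.094
20000,1,1.50,1.216,1.155,1.116,1.093
20000,4,1.40,1.171,1.123,1.091,1.073
20000,10,1.38,1.161,1.115,1.086,1.068
20000,50,1.37,1.155,1.111,1.082,1.066
40000,1,1.34,1.150,1.108,1.081,1.065
40000,4,1.27,1.119,1.086,1.064,1.051
40000,10,1.26,1.112,1.080,1.060,1.048
40000,50,1.25,1.108,1.077,1.058,1.046
80000,1,1.24,1.105,1.076,1.057,1.046
80000,4,1.19,1.083,1.060,1.045,1.036
80000,10,1.18,1.078,1.056,1.042,1.034
80000,50,1.17,1.075,1.054,1.040,1.032
160000,1,1.165,1.074,1.053,1.04,1.032
160000,4,1.131,1.058,1.042,1.031,1.025
160000,10,1.123,1.055,1.04,1.03,1.024
160000,50,1.118,1.053,1.038,1.028,1.023
320000,1,1.115,1.052,1.037,1.028,1.022
320000,4,1.091,1.041,1.03,1.022,1.018
320000,10,1.086,1.038,1.028,1.021,1.017
320000,50,1.083,1.037,1.027,1.02,1.016
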