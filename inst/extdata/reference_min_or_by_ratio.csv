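j,or_1.05,or_1.1,or_1.2,or_1.3,or_1.5,or_1.75,or_2,pct_reduction_vs_j1,pct_reduction_vs_j4
1,1.05,1.1,1.2,1.3,1.5,1.75,2,0.0,-26.5
2,1.043,1.087,1.17,1.26,1.43,1.65,1.87,13.4,-9.5
3,1.041,1.082,1.16,1.25,1.41,1.61,1.82,18.4,-3.3
4,1.04,1.079,1.16,1.24,1.40,1.59,1.79,20.9,0.0
5,1.039,1.077,1.16,1.23,1.39,1.58,1.78,22.5,2.0
10,1.037,1.074,1.15,1.22,1.37,1.56,1.74,25.8,6.2
20,1.036,1.072,1.15,1.22,1.36,1.54,1.73,27.5,8.3
50,1.036,1.071,1.14,1.21,1.36,1.54,1.71,28.6,9.7
100,1.036,1.071,1.14,1.21,1.36,1.53,1.71,28.9,10.1
1000,1.035,1.071,1.14,1.21,1.35,1.53,1.71,29.3,10.5
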