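"fiber_id","angle_deg","length_um","width_um","straightness"
1,163.374,41.85,1.89,0.907
2,114.983,42.67,1.18,0.9
3,138.178,18.59,2,0.831
4,144.922,38.73,1.31,0.879
5,139.207,31.74,1.82,0.978
6,126.447,27.21,2,0.988
7,166.888,35.25,0.94,0.891
8,126.734,12.98,0.65,0.849
9,179.561,32.31,0.84,0.878
10,127.532,34.09,1.82,0.875
11,161.722,24.94,2.28,0.839
12,6.266,34.61,1.59,0.996
13,94.378,42.58,1.68,0.909
14,122.13,17.45,0.95,0.837
15,125.767,25.1,1.56,0.858
16,144.999,42.78,0.92,0.987
17,121.994,44.19,1.41,0.873
18,62.689,12.35,1.17,0.938
19,68.088,25.57,0.81,0.982
20,162.103,28.73,0.93,0.998
21,121.434,41.45,1.91,0.897
22,84.567,13.13,1.34,0.891
23,124.802,44.59,1.35,0.846
24,159.467,43.03,1.46,0.87
25,176.48,11.05,1.37,0.922
26,118.338,27.03,0.85,0.988
27,122.668,22.44,2.08,0.885
28,85.021,41.51,1.67,0.972
29,140.602,24.54,2.03,0.95
30,113.1,38.93,1.98,0.955
31,140.486,35.29,2.25,0.986
32,146.721,38.01,2.15,0.82
33,154.978,22.36,1.17,0.849
34,113.877,33.35,1.07,0.892
35,141.724,8.15,1.94,0.942
36,86.175,38.82,1.95,0.906
37,109.489,8.27,2.25,0.916
38,107.827,15.68,2.03,0.877
39,68.745,41.54,0.84,0.967
40,130.003,30.64,1.12,0.873
41,134.25,22.04,0.95,0.894
42,120.074,24.12,2.01,0.836
43,148.054,9.38,0.83,0.964
44,110.932,44.02,0.83,0.885
45,94.893,23.97,0.73,0.827
46,139.92,43.43,0.7,0.827
47,108.815,40.85,1.56,0.992
48,165.203,31.68,0.8,0.887
49,118.314,43.93,1.94,0.965
50,145.491,30.9,1.92,0.984
51,137.148,20.34,2.19,0.899
52,109.504,20.83,1.53,0.924
53,168.493,22.74,2.13,0.833
54,145.172,37.03,1.4,0.85
55,131.344,9.44,0.88,0.953
56,136.014,35.71,1.4,0.906
57,146.082,33.06,2.34,0.943
58,131.346,14.34,1.47,0.991
59,54.273,17.66,1.05,0.91
60,136.222,27.03,1.07,0.905
61,119.919,33,1.58,0.921
62,133.731,44.36,1.77,0.937
63,143.646,36.1,1.21,0.87
64,164.093,28.96,0.71,0.996
65,110.918,39.44,1.41,0.936
66,161.664,15.01,2.11,0.925
67,137.496,18.04,1.63,0.931
68,155.063,38.64,1.24,0.987
69,152.118,33.65,1.59,0.89
70,147.122,16.9,2.21,0.872
71,103.022,9.59,1.48,0.836
72,126.845,13.2,0.91,0.878
73,144.688,16.01,1.58,0.956
74,105.262,25.74,2.33,0.839
75,115.529,15.3,1.16,0.948
76,143.625,34.62,2.08,0.994
77,148.304,8.29,1.15,0.856
78,140.694,21.89,0.93,0.84
79,106.956,27.03,0.69,0.83
80,101.605,8.06,1.04,0.969
81,166.918,29.52,1.23,0.925
82,135.548,13.84,0.89,0.905
83,131.311,21.28,1.15,0.886
84,126.078,31.89,0.63,0.87
85,99.242,36.71,2.39,0.928
86,144.4,28.85,2.05,0.967
87,123.672,16.65,0.76,0.838
88,124.531,11.33,2.17,0.993
89,152.434,11.17,1.6,0.85
90,149.644,19.29,1.36,0.835
91,163.903,32.69,0.72,0.975
92,117.196,8.01,1.61,0.914
93,145.359,15.72,0.73,0.938
94,163.878,42.52,0.98,0.861
95,101.33,42.25,1.59,0.95
96,107.58,35.16,1.47,0.908
97,100.807,20.32,0.89,0.994
98,92.62,27.06,0.87,0.983
99,131.1,35.53,1.5,0.919
100,145.43,30.91,2.29,0.834
101,159.124,31.17,1.2,0.824
102,155.219,16.03,0.94,0.912
103,104.02,16.01,1.09,0.934
104,175.312,22.39,1.56,0.895
105,112.431,42.87,0.64,0.978
106,131.738,43.62,2.04,0.839
107,118.544,35.37,0.8,0.996
108,126.041,35.13,1.57,0.868
109,133.805,27.82,1.63,0.835
110,132.079,8.08,1.71,0.889
111,128.473,30.53,1.89,0.842
112,131.802,38.96,0.82,0.925
113,116.964,35.81,1.16,0.863
114,116.495,24.75,2.3,0.95
115,87.573,27.82,1.5,0.846
116,119.542,27.88,0.84,0.848
117,116.284,8.05,2.16,0.867
118,16.647,21.16,0.97,0.96
119,95.047,30.65,2.27,0.897
120,132.531,38.67,2.2,0.831
121,91.759,21.2,0.85,0.841
122,92.339,23.19,2.01,0.907
123,132.218,29.22,1.42,0.996
124,104.184,29.82,0.84,0.966
125,129.054,34.63,2.19,0.918
126,118.394,22.61,1.21,0.833
127,113.758,42.01,1.17,0.904
128,78.483,43.62,1.33,0.881
129,98.481,16.64,1.46,0.944
130,133.588,34.81,1.26,0.913
131,143.291,41.43,1.44,0.913
132,116.778,30.33,0.69,0.918
133,129.102,31.37,0.94,0.901
134,157.172,42.68,2.37,0.835
135,165.096,39.47,1.19,0.987
136,101.672,29.45,0.91,0.823
137,126.167,38.39,1.48,0.895
138,159.137,12.21,0.63,0.861
139,117.357,36.29,1.21,0.838
140,127.788,31.07,0.65,0.907
141,126.947,13.49,2.16,0.937
142,106.908,10.97,1.92,0.986
143,117.983,25.17,1.17,0.885
144,128.364,36.84,1.3,0.974
145,118.753,35.14,1.2,0.874
146,156.935,38.24,0.76,0.904
147,117.075,14.3,1.96,0.846
148,118.271,42.95,1.69,0.965
149,146.522,18.86,0.86,0.94
150,102.691,13.52,0.66,0.831
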