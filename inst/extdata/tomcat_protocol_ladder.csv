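label,s1,s2,s3,total_projections,dose_fraction_pct,measured_quality_pct
A,NA,NA,NA,13534,100,NA
B,5244,5244,5244,15732,116,100
C,5244,2622,5244,13110,97,89
D,4370,4370,4370,13110,97,85
E,4370,2185,4370,10925,81,87
F,3934,3934,3934,11802,87,80
G,3934,1967,3934,9835,73,84
H,3496,3496,3496,10488,77,78
I,3496,1748,3496,8740,65,80
J,3060,3060,3060,9180,68,76
K,3060,1530,3060,7650,57,75
L,2622,2622,2622,7866,58,72
M,2622,1311,2622,6555,48,69
N,2186,2186,2186,6558,48,67
O,2185,1093,2185,5463,40,62
P,1748,1748,1748,5244,39,61
Q,1748,874,1748,4370,32,55
R,1312,1312,1312,3936,29,46
S,874,874,874,2622,19,21
T,874,437,874,2185,16,20
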