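mutant,v1,v1_sd,v2,v2_sd,n
WT,3.84,1.45,4.66,1.38,8
P454A,2.88,0.80,5.39,0.43,3
V455A,0.82,0.05,0.25,0.01,3
T456A,0.59,0.04,0.24,0.06,3
G457A,3.47,1.11,6.02,1.19,3
R458A,0.63,0.07,0.37,0.03,3
V459A,5.65,0.68,6.85,1.44,3
E460A,6.54,0.83,5.36,1.39,3
E461A,7.45,0.65,5.06,0.59,3
K462A,4.46,0.92,5.15,0.24,3
P463A,2.90,0.69,4.78,1.26,3
P464A,2.83,0.94,4.73,1.21,3
N465A,2.25,1.03,4.56,0.51,3
P466A,0.47,0.01,0.34,0.02,3
M467A,2.17,0.06,4.57,0.44,3
E468A,3.82,0.55,6.23,0.88,3
G469A,0.63,0.08,0.26,0.05,3
trunc452,0.86,0.22,0.39,0.03,3
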