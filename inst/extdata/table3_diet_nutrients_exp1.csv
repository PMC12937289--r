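diet_id,dm,ge,cp,ash,ee,ca,p
basal,86.94,14.96,7.35,3.41,3.04,0.73,0.43
esbm1,89.61,15.78,21.65,5.45,2.31,0.83,0.6
esbm2,88.82,15.7,20.35,5.03,2.27,0.83,0.57
esbm3,88.88,15.85,19.15,5.04,2.32,0.88,0.55
esbm4,88.16,15.92,19.62,4.98,2.33,0.88,0.57
esbm5,89.01,16.43,21.58,4.16,2.14,0.85,0.53
esbm6,89.15,15.96,19.3,5.19,2.34,0.86,0.56
esbm7,89.22,15.85,19.21,4.7,2.86,0.83,0.54
esbm8,88.98,15.54,20.41,5.69,2.44,0.9,0.58
esbm9,87.73,15.42,16.91,5.55,2.18,0.84,0.53
esbm10,87.55,15.34,17.44,5.1,2.21,0.81,0.52
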