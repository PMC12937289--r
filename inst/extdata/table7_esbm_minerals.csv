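ingredient_id,ca,p,cu,zn,fe,mn,na,mg,k
esbm1,0.31,0.75,8.22,38.92,226.36,45.03,1.48,0.36,1.97
esbm2,0.32,0.67,11.9,53.97,280.93,40.08,0.04,0.32,2.22
esbm3,0.37,0.63,13.1,50.18,262.05,37.27,0.05,0.31,2.13
esbm4,0.34,0.64,11.32,48.2,208.14,114.63,0.1,0.35,2.15
esbm5,0.37,0.54,9.94,57.15,212.6,42.68,0.04,0.19,0.99
esbm6,0.3,0.61,11.12,45.21,335.9,31.78,0.62,0.35,2.08
esbm7,0.31,0.6,12.84,47.17,400.96,38.54,0.07,0.27,2.05
esbm8,0.47,0.72,11.33,53.82,256.53,35.63,0.01,0.5,2.43
esbm9,0.27,0.51,10.46,40.9,198.56,26.31,1.6,0.27,1.78
esbm10,0.27,0.54,10.32,40.52,231.85,27.3,0.99,0.28,1.87
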