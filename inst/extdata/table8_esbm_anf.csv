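ingredient_id,phytic_acid,glycinin,b_conglycinin,trypsin_inhibitor,lectin
esbm1,0.25,49.19,19.85,16.17,8.83
esbm2,0.18,108.48,122.7,11.48,9.65
esbm3,0.19,78.59,20.26,14.87,8.77
esbm4,0.02,18.52,1.21,14.37,9.13
esbm5,0.14,159.3,163.04,15.57,10.87
esbm6,0.14,40.59,2.59,17.05,8.45
esbm7,0.27,173.5,140.45,16.66,12.9
esbm8,0.26,16.11,1.65,14.27,9.42
esbm9,0.25,53.83,27.26,7,10.71
esbm10,0.25,28.97,0.99,6.74,9.23
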