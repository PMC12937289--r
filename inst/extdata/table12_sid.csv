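aa,esbm1,esbm2,esbm3,esbm4,esbm5,esbm6,esbm7,esbm8,esbm9,esbm10
lys,76.43,78.4,72.11,81.8,92.12,73.87,95.64,71.19,88.03,87.61
met,72.75,86.54,79.12,87.75,95.02,77.48,87.57,45.59,95.76,85.99
thr,67.43,79.53,69.31,79.67,88.68,68.71,90.4,59.67,82.23,76.29
trp,42.3,52.1,33.91,52.77,74.13,40.13,71.95,15.4,65.01,58.4
val,72.2,83.92,76.22,84.42,90.79,70.45,92.99,69.39,88.23,83.65
phe,79.16,87.63,80.44,88.2,92.26,81.2,94.55,67.25,90.23,87.93
ile,74.27,86.68,78.29,87.19,92.34,73.65,94.56,70.5,88.89,84.74
leu,75.94,86.38,78.76,86.97,91.49,73.33,93.63,71.74,89.39,85.49
arg,89.3,95.65,91.6,96.54,99.88,89.37,100.8,68.38,97.5,96.71
his,75.68,86.92,79.14,86.56,93.26,77.11,95.61,64.27,88.61,85.12
ala,69.46,78.91,73.9,82.17,89.4,68.49,92.75,70.44,86.59,80.6
asp,62.56,82.84,71.88,79.7,91.25,62.2,91.91,53.27,81.17,79.24
cys,57.36,79.42,69.98,73.32,89.54,47.48,92.03,64.28,86.24,82.21
glu,72.24,83.55,73.75,79.25,90.76,75.96,94.11,63.54,84.81,80.22
gly,73.58,79.89,73.84,86.55,93.25,68.2,98.71,64.75,92.45,84.12
pro,146.51,140.12,143.16,155.95,146.14,114.86,165.99,119.87,163.27,163.93
ser,74.12,86.97,77.41,84.87,92.84,73.89,94.1,67.68,84.57,83.01
tyr,79.47,85.85,80.02,88.03,94.17,78.11,94.03,67.54,90.55,89.12
taa,76.9,87.06,79.25,87.41,94.67,75.19,96.56,67.36,90.91,87.57
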