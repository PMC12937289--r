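item,basis,measure,sample,value
diet,as_fed,de,esbm1,14.16
diet,as_fed,de,esbm2,14.26
diet,as_fed,de,esbm3,14.18
diet,as_fed,de,esbm4,14.68
diet,as_fed,de,esbm5,15.02
diet,as_fed,de,esbm6,14.47
diet,as_fed,de,esbm7,14.42
diet,as_fed,de,esbm8,13.53
diet,as_fed,de,esbm9,13.95
diet,as_fed,de,esbm10,13.74
diet,as_fed,me,esbm1,13.78
diet,as_fed,me,esbm2,13.82
diet,as_fed,me,esbm3,13.72
diet,as_fed,me,esbm4,14.35
diet,as_fed,me,esbm5,14.75
diet,as_fed,me,esbm6,13.98
diet,as_fed,me,esbm7,14.07
diet,as_fed,me,esbm8,13.08
diet,as_fed,me,esbm9,13.6
diet,as_fed,me,esbm10,13.52
diet,dry_matter,de,esbm1,14.78
diet,dry_matter,de,esbm2,15.37
diet,dry_matter,de,esbm3,15.16
diet,dry_matter,de,esbm4,16.22
diet,dry_matter,de,esbm5,16.13
diet,dry_matter,de,esbm6,15.46
diet,dry_matter,de,esbm7,15
diet,dry_matter,de,esbm8,14.53
diet,dry_matter,de,esbm9,15.59
diet,dry_matter,de,esbm10,15.56
diet,dry_matter,me,esbm1,14.38
diet,dry_matter,me,esbm2,14.9
diet,dry_matter,me,esbm3,14.66
diet,dry_matter,me,esbm4,15.85
diet,dry_matter,me,esbm5,15.84
diet,dry_matter,me,esbm6,14.94
diet,dry_matter,me,esbm7,14.63
diet,dry_matter,me,esbm8,14.04
diet,dry_matter,me,esbm9,15.2
diet,dry_matter,me,esbm10,15.31
diet,dry_matter,me_de_ratio,esbm1,97.32
diet,dry_matter,me_de_ratio,esbm2,96.93
diet,dry_matter,me_de_ratio,esbm3,96.76
diet,dry_matter,me_de_ratio,esbm4,97.76
diet,dry_matter,me_de_ratio,esbm5,98.22
diet,dry_matter,me_de_ratio,esbm6,96.63
diet,dry_matter,me_de_ratio,esbm7,97.56
diet,dry_matter,me_de_ratio,esbm8,96.62
diet,dry_matter,me_de_ratio,esbm9,97.51
diet,dry_matter,me_de_ratio,esbm10,98.38
ingredient,as_fed,de,esbm1,14.96
ingredient,as_fed,de,esbm2,15.29
ingredient,as_fed,de,esbm3,15.01
ingredient,as_fed,de,esbm4,16.69
ingredient,as_fed,de,esbm5,17.81
ingredient,as_fed,de,esbm6,15.99
ingredient,as_fed,de,esbm7,15.82
ingredient,as_fed,de,esbm8,12.87
ingredient,as_fed,de,esbm9,14.26
ingredient,as_fed,de,esbm10,13.55
ingredient,as_fed,me,esbm1,14.25
ingredient,as_fed,me,esbm2,14.39
ingredient,as_fed,me,esbm3,14.03
ingredient,as_fed,me,esbm4,16.15
ingredient,as_fed,me,esbm5,17.48
ingredient,as_fed,me,esbm6,14.93
ingredient,as_fed,me,esbm7,15.21
ingredient,as_fed,me,esbm8,11.91
ingredient,as_fed,me,esbm9,13.66
ingredient,as_fed,me,esbm10,13.37
ingredient,dry_matter,de,esbm1,15.61
ingredient,dry_matter,de,esbm2,16.48
ingredient,dry_matter,de,esbm3,16.04
ingredient,dry_matter,de,esbm4,18.43
ingredient,dry_matter,de,esbm5,19.13
ingredient,dry_matter,de,esbm6,17.08
ingredient,dry_matter,de,esbm7,16.75
ingredient,dry_matter,de,esbm8,13.82
ingredient,dry_matter,de,esbm9,15.94
ingredient,dry_matter,de,esbm10,15.34
ingredient,dry_matter,me,esbm1,14.88
ingredient,dry_matter,me,esbm2,15.51
ingredient,dry_matter,me,esbm3,15.01
ingredient,dry_matter,me,esbm4,17.84
ingredient,dry_matter,me,esbm5,18.77
ingredient,dry_matter,me,esbm6,15.94
ingredient,dry_matter,me,esbm7,16.1
ingredient,dry_matter,me,esbm8,12.79
ingredient,dry_matter,me,esbm9,15.27
ingredient,dry_matter,me,esbm10,15.14
ingredient,dry_matter,me_de_ratio,esbm1,95.3
ingredient,dry_matter,me_de_ratio,esbm2,94.14
ingredient,dry_matter,me_de_ratio,esbm3,93.53
ingredient,dry_matter,me_de_ratio,esbm4,96.81
ingredient,dry_matter,me_de_ratio,esbm5,98.16
ingredient,dry_matter,me_de_ratio,esbm6,93.38
ingredient,dry_matter,me_de_ratio,esbm7,96.15
ingredient,dry_matter,me_de_ratio,esbm8,92.44
ingredient,dry_matter,me_de_ratio,esbm9,95.84
ingredient,dry_matter,me_de_ratio,esbm10,98.68
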