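component,corn_basal_pct,esbm_diet_pct
corn,97,67.9
enzymolytic_soybean_meal,0,29.1
dicalcium_phosphate,1.2,1.2
limestone,1,1
sodium_chloride,0.3,0.3
vitamin_mineral_premix,0.5,0.5
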