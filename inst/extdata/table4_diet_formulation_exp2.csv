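component,amount_pct
enzymolytic_soybean_meal,40
cornstarch,44.45
sucrose,10
soybean_oil,3
dicalcium_phosphate,1.1
limestone,0.7
sodium_chloride,0.3
titanium_dioxide,0.2
vitamin_mineral_premix,0.25
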