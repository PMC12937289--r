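aa,iaa_g_per_kg_dmi
lys,5.09
met,0.6
thr,6.19
trp,0.63
val,5.09
phe,3.48
ile,4.36
leu,6.38
arg,7.49
his,2.19
ala,8.23
asp,9.69
cys,1.2
glu,12.9
gly,21.04
pro,84.34
ser,6.65
tyr,2.95
taa,192.18
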