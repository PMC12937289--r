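basis,de_d,me_d,source
as_fed,13.405,13.172,back_solved_synthetic
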