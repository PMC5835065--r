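culture,guild,partner_present,mu_max_h,ks_uM,lag50_h,ks_derived
Culture01,AOB,TRUE,0.028,25.9,23,FALSE
Culture02,AOB,FALSE,0.021,71.8,250,FALSE
Culture03,NOB,FALSE,0.0052,38,88,TRUE
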