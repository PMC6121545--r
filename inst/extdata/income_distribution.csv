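bracket,share,mean_income
<25K,0.18,15000
25-<50K,0.22,37500
50-<100K,0.35,72000
>=100K,0.25,150000
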