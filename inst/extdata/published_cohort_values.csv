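quantity,value
african_grand_mean_kpa,946
asian_grand_mean_kpa,567
fore_mean_kpa,264
fore_se_kpa,5.31
hind_mean_kpa,246
hind_se_kpa,5.09
asian_mean_froude,0.10
asian_weighted_mean_mass_kg,1156
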