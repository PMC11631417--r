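trait,s0_mean,s1_mean
heterozygosity,0.356,0.192
yield_g_per_plant,727.6,369.6
count_fruit,24.5,16.4
weight_g_per_fruit,29.7,22.8
firmness_kg_force,0.81,0.86
tss_pct,8.9,10.2
ta_pct,0.75,0.81
tss_ta,11.9,12.7
anc_ug_ml,104.2,111.5
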