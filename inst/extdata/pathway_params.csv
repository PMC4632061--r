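key,value
influx_ali,1
influx_ind,0.6
k_elong,1
k_cyp79f1,0.6
k_cyp79f2,1.2
k_cyp83a1,2
k_cyp79b,1.5
k_cyp83b1,2
kcat_sur1,0.9
km_sur1_ali,0.1
km_sur1_ind,0.5
k_late_ali,3
k_late_ind,3
k_cyp81f2,0.8
k_mod1m,0.8
d_product,0.25
d_precursor,0.5
d_intermediate,0.05
d_committed,0.4
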