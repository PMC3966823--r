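name,lower_g_per_ha,upper_g_per_ha
Low,0,1.25
Low-Medium,1.25,4
Medium,4,10.5
Medium-High,10.5,26
High,26,70
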