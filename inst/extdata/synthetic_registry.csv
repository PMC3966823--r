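crop_code,crop_name,ai,seed_loading_g_per_kg,seeding_rate_kg_per_ha,resolved_rate_g_per_ha,treated_fraction
1,canola,thiamethoxam,4.2,5,21,0.45
1,canola,clothianidin,,,21,0.45
2,wheat,thiamethoxam,,,13,0.30
2,wheat,imidacloprid,,,13,0.05
3,barley,thiamethoxam,0.13,100,13,0.35
4,oat,thiamethoxam,,,12,0.20
5,pea,thiamethoxam,,,70,0.25
6,bean,thiamethoxam,,,26,0.30
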