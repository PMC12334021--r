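criterion,weight,direction
pct_affected_corridors_gt150,0.13,min
pct_affected_cores_gt150,0.2,min
pct_affected_core_area,0.25,min
para_mn_cores_1km,0.12,min
enn_mn_cores_1km,0.12,min
para_mn_selected,0.06,min
enn_mn_selected,0.12,min
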