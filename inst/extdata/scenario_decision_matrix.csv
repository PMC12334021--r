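scenario,demand_ha,pct_affected_corridors_gt150,pct_affected_cores_gt150,pct_affected_core_area,para_mn_cores_1km,enn_mn_cores_1km,para_mn_selected,enn_mn_selected
Usual Growth,23850,69.5,13,0.7,253.75,422.06,110.58,1614.78
Compact Growth,23850,69.9,12.9,0.66,250.09,424.64,109.42,1541.66
Social Equity Growth,23850,74,1,0.54,250.33,424.18,114.55,980.18
Compact-Social Equity Growth,23850,74,1,0.47,250.25,424.27,114.65,1045.36
MSPA-Informed Growth,23850,73,3.6,0.56,246.93,421.13,131.06,1089.63
MSPA-Informed Compact Growth,23850,81,6.6,0.4,245.92,417.68,148.09,1000.57
MSPA-Informed Social Equity Growth,23850,74.6,1.4,0.51,246.05,418.69,142.29,1110.93
MSPA-Informed Compact-Social Equity Growth,23850,79.3,0.6,0.44,243.27,414.34,164.89,987.73
Usual Growth,2385,69.5,13,0.7,240.93,408.16,275.40,1297.87
Compact Growth,2385,69.9,12.9,0.66,240.49,407.76,151.94,2833.66
Social Equity Growth,2385,74,1,0.54,239.69,403.82,285.90,1468.18
Compact-Social Equity Growth,2385,74,1,0.47,239.69,403.82,114.65,1045.36
MSPA-Informed Growth,2385,73,3.6,0.56,237.95,408.87,167.18,2942.93
MSPA-Informed Compact Growth,2385,81,6.6,0.4,238.35,408.69,155.59,2500.26
MSPA-Informed Social Equity Growth,2385,74.6,1.4,0.51,238.61,406.53,267.57,1292.90
MSPA-Informed Compact-Social Equity Growth,2385,79.3,0.6,0.44,238.65,406.93,287.30,2314.34
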