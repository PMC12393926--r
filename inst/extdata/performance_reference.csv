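"diet","indicator","mean","sd"
"CTRL","fbw_g",47.8,1.43
"ORG","fbw_g",42.6,0.32
"ECO","fbw_g",48.8,1.62
"CTRL","sgr_per_day",0.019,0.001
"ORG","sgr_per_day",0.017,0
"ECO","sgr_per_day",0.019,0
"CTRL","fi_g_per_fish",36.3,0.91
"ORG","fi_g_per_fish",34.7,0.83
"ECO","fi_g_per_fish",38.3,0.47
"CTRL","fcr",1.1,0.06
"ORG","fcr",1.2,0.03
"ECO","fcr",1.1,0.04
"CTRL","per",1.9,0.1
"ORG","per",1.6,0.04
"ECO","per",1.9,0.07
"CTRL","vsi_pct",7.7,0.71
"ORG","vsi_pct",8.2,0.16
"ECO","vsi_pct",7.6,0.27
"CTRL","hsi_pct",1.1,0.05
"ORG","hsi_pct",1.2,0.11
"ECO","hsi_pct",1.2,0.02
"CTRL","k",1.4,0.03
"ORG","k",1.5,0.04
"ECO","k",1.5,0.02
"CTRL","survival_pct",96.7,0.1
"ORG","survival_pct",96.7,1.92
"ECO","survival_pct",92.9,3.51
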