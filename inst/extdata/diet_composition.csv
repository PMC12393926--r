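"diet","dm","ash","crude_protein","crude_fat","total_p","gross_energy","marker"
"CTRL",94.31,7.76,50.61,17.66,1.1,21.8,0.02
"ORG",96.91,7.03,51.05,17.93,1.02,22.2,0.02
"ECO",95.56,5.76,51.4,17.8,1.31,22.54,0.02
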