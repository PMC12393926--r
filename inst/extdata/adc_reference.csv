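"diet","constituent","mean","sd"
"CTRL","dm",80.6,3.53
"ORG","dm",79.2,3.1
"ECO","dm",61.8,9.85
"CTRL","protein",94.7,1.12
"ORG","protein",96.6,0.52
"ECO","protein",89.6,2.86
"CTRL","lipid",98.5,0.28
"ORG","lipid",98.3,0.2
"ECO","lipid",96.4,0.71
"CTRL","phosphorus",66.6,8.95
"ORG","phosphorus",77.5,2.77
"ECO","phosphorus",67.2,7.76
"CTRL","energy",94,1.31
"ORG","energy",94.3,0.69
"ECO","energy",86.4,3.73
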