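"diet","constituent","mean","sd"
"CTRL","protein",28.1,2.07
"ORG","protein",25.8,0.88
"ECO","protein",27.8,1.56
"CTRL","lipid",48.9,6.43
"ORG","lipid",47.1,2.42
"ECO","lipid",48.2,1.61
"CTRL","phosphorus",65.4,10.31
"ORG","phosphorus",78.6,7.59
"ECO","phosphorus",67.4,6.82
"CTRL","energy",28.7,2.2
"ORG","energy",27.2,1.57
"ECO","energy",27.7,1.42
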