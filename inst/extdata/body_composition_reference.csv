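"pool","dm","protein","lipid","ash","phosphorus","energy"
"initial",26.8,14.9,7,3.9,0.9,5.8
"CTRL",29.5,15.3,8.7,4.2,0.8,6.5
"ORG",30.2,15.8,9.3,4.4,1,6.9
"ECO",30.1,15.8,8.9,4.2,1,6.7
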