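"gene","diet","mean","sd"
"sod","CTRL",1,0.25
"sod","ORG",1,0.24
"sod","ECO",1.1,0.13
"cat","CTRL",1.5,0.87
"cat","ORG",2,0.92
"cat","ECO",1.9,0.51
"gpx","CTRL",0.9,0.47
"gpx","ORG",0.9,0.64
"gpx","ECO",1.3,0.24
"nrf2","CTRL",1.1,0.52
"nrf2","ORG",0.9,0.35
"nrf2","ECO",0.9,0.09
"il1b","CTRL",1,0.14
"il1b","ORG",0.8,0.32
"il1b","ECO",0.6,0.22
"igm","CTRL",0.8,0.47
"igm","ORG",13.8,0.7
"igm","ECO",13.2,0.8
"cox2","CTRL",1.1,0.27
"cox2","ORG",1.1,0.4
"cox2","ECO",0.9,0.34
"muc13","CTRL",1.1,0.38
"muc13","ORG",1.1,0.33
"muc13","ECO",1.8,0.37
"cldn12","CTRL",1.2,0.11
"cldn12","ORG",1.4,0.62
"cldn12","ECO",1,0.11
"tjp2","CTRL",1.1,0.63
"tjp2","ORG",1.8,0.53
"tjp2","ECO",1.7,0.73
"ocl","CTRL",1.2,0.37
"ocl","ORG",1.6,0.51
"ocl","ECO",1.9,0.2
"pcna","CTRL",1.1,0.15
"pcna","ORG",1.2,0.34
"pcna","ECO",1.2,0.37
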