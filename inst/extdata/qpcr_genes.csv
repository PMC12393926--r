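"gene","efficiency","role","panel"
"sod",128.6,"target","oxidative"
"cat",121.2,"target","oxidative"
"gpx",113.4,"target","oxidative"
"nrf2",111.3,"target","oxidative"
"il1b",96.5,"target","immune"
"igm",117.8,"target","immune"
"cox2",120,"target","immune"
"muc13",109.9,"target","integrity"
"cldn12",101,"target","integrity"
"tjp2",107.8,"target","integrity"
"ocl",108.1,"target","integrity"
"pcna",119,"target","integrity"
"ef1a",110.9,"reference","housekeeping"
"r18s",114.5,"reference","housekeeping"
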