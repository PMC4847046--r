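id,x,y,value,instrument,analyte,role,ec,ph
89,146,72.8,636,primary,Cu,train,44,5.76
90,147,40.3,4437,primary,Cu,train,17.8,5.69
91,179.4,41.4,1080,primary,Cu,train,26.3,5.04
92,155.7,80.9,17,primary,Cu,train,27.1,4.72
93,30.3,96,57,primary,Cu,train,32.4,4.56
94,59.7,52.1,1338,primary,Cu,train,36.4,5.01
95,42,13.5,33,primary,Cu,train,51.3,4.8
96,154,68.2,29,primary,Cu,train,30.1,5.57
97,29.5,122.4,344,primary,Cu,train,27.6,4.68
98,29.5,85.4,1535,primary,Cu,train,13.7,5.32
99,18.7,54.5,4041,primary,Cu,train,22.4,4.93
100,15.1,81.6,48,primary,Cu,train,48.3,5.09
V1,106.1,130,1517,primary,Cu,validation,29.7,4.95
V2,26.3,73.6,2364,primary,Cu,validation,26.7,5.01
V3,146.2,29,1176,primary,Cu,validation,35.4,5.2
V4,143.9,81,3814,primary,Cu,validation,30.3,4.95
V5,173.2,139.6,334,primary,Cu,validation,38.2,4.89
V6,103.3,48.9,48,primary,Cu,validation,59.6,4.88
V7,166.9,119.9,2454,primary,Cu,validation,65,4.41
V8,89.1,48,1368,primary,Cu,validation,31.7,5.1
V9,35,31,69,primary,Cu,validation,14.5,5.47
V10,89,11.8,589,primary,Cu,validation,37.1,5.21
V11,188.9,39.4,567,primary,Cu,validation,50.9,5.38
89,146,72.8,188,primary,Pb,train,44,5.76
90,147,40.3,811,primary,Pb,train,17.8,5.69
91,179.4,41.4,223,primary,Pb,train,26.3,5.04
92,155.7,80.9,26,primary,Pb,train,27.1,4.72
93,30.3,96,81,primary,Pb,train,32.4,4.56
94,59.7,52.1,402,primary,Pb,train,36.4,5.01
95,42,13.5,59,primary,Pb,train,51.3,4.8
96,154,68.2,46,primary,Pb,train,30.1,5.57
97,29.5,122.4,94,primary,Pb,train,27.6,4.68
98,29.5,85.4,872,primary,Pb,train,13.7,5.32
99,18.7,54.5,1924,primary,Pb,train,22.4,4.93
100,15.1,81.6,29,primary,Pb,train,48.3,5.09
V1,106.1,130,602,primary,Pb,validation,29.7,4.95
V2,26.3,73.6,562,primary,Pb,validation,26.7,5.01
V3,146.2,29,262,primary,Pb,validation,35.4,5.2
V4,143.9,81,1545,primary,Pb,validation,30.3,4.95
V5,173.2,139.6,114,primary,Pb,validation,38.2,4.89
V6,103.3,48.9,29,primary,Pb,validation,59.6,4.88
V7,166.9,119.9,695,primary,Pb,validation,65,4.41
V8,89.1,48,536,primary,Pb,validation,31.7,5.1
V9,35,31,32,primary,Pb,validation,14.5,5.47
V10,89,11.8,132,primary,Pb,validation,37.1,5.21
V11,188.9,39.4,187,primary,Pb,validation,50.9,5.38
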