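"electrode","x_cm","y_cm"
"E1",-0.1,-0.3
"E2",0.1,-0.3
"E3",-0.3,-0.1
"E4",-0.1,-0.1
"E5",0.1,-0.1
"E6",0.3,-0.1
"E7",-0.3,0.1
"E8",-0.1,0.1
"E9",0.1,0.1
"E10",0.3,0.1
"E11",-0.1,0.3
"E12",0.1,0.3
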