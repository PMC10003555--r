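lane,condition,replicate,band,intensity,length_nt
L1,adenine_0mM,1,T,8420,100
L1,adenine_0mM,1,FL,1510,120
L2,adenine_0mM,2,T,7980,100
L2,adenine_0mM,2,FL,1305,120
L3,adenine_0mM,3,T,8655,100
L3,adenine_0mM,3,FL,1620,120
L4,adenine_1mM,1,T,5260,100
L4,adenine_1mM,1,FL,4180,120
L5,adenine_1mM,2,T,5030,100
L5,adenine_1mM,2,FL,4415,120
L6,adenine_1mM,3,T,5495,100
L6,adenine_1mM,3,FL,3950,120
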