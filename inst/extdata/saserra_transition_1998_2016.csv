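from,cork oak forest,other forest,agricultural,natural pasture,urban
cork oak forest,38,10,0,8,0
other forest,5,26,0,7,0
agricultural,4,2,2,10,0
natural pasture,1,2,0,32,0
urban,0,0,0,0,2
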