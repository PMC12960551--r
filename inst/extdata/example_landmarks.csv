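id,x,y,z
HEEL,0,30,0
MT1,-47.5,180,0
MT5,47.5,180,0
ARCH,-10.5,100,15
MED_MAL,-27.5,50,65
LAT_MAL,27.5,50,65
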