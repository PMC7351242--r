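g1,g2,g3,g4,g5,g6,g7,g8,g9,g10,g11,g12,g13,g14,g15,g16
0,1,0,0,0,0,-1,0,0,0,0,0,0,-1,0,0
0,0,0,0,0,0,0,1,0,0,0,0,0,-1,0,0
0,0,0,0,-1,0,0,0,0,0,0,0,1,0,0,0
-1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
1,0,0,0,0,0,0,0,0,0,0,0,-1,0,0,0
0,0,0,0,-1,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0
0,0,-1,0,0,0,1,0,0,0,0,0,0,0,0,0
-1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,-1,0,1,0,0,0
1,0,0,-1,0,1,0,0,0,0,0,0,-1,0,0,0
0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
-1,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0
0,0,0,1,-1,0,0,0,1,1,-1,0,0,0,0,0
0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
-1,-1,1,1,-1,0,0,-1,0,0,-1,1,1,1,0,0
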