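glycan,composition
g1,Hex:5 HexNAc:4 dHex:1
g2,Hex:3 HexNAc:6
g3,Hex:7 HexNAc:2
g4,Hex:6 HexNAc:6
g5,Hex:8 HexNAc:8 dHex:2
g6,Hex:9 HexNAc:8 dHex:1
g7,Hex:3 HexNAc:2
g8,Hex:5 HexNAc:4 NeuAc:1
g9,Hex:5 HexNAc:5 dHex:4
g10,Hex:4 HexNAc:3 dHex:1
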