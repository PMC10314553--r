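alias,canonical
Basion,Ba
Ba,Ba
PNS,PNS
Posterior Nasal Spine,PNS
C2I,C2I
C2 inferior,C2I
C4S,C4S
C4 superior,C4S
Condylion R,CoR
Condylion Right,CoR
Co R,CoR
CoR,CoR
Condylion L,CoL
Condylion Left,CoL
Co L,CoL
CoL,CoL
Gonion R,GoR
Gonion Right,GoR
Go R,GoR
GoR,GoR
Gonion L,GoL
Gonion Left,GoL
Go L,GoL
GoL,GoL
B point,B
B-point,B
B,B
Porion R,PoR
Porion Right,PoR
Po R,PoR
PoR,PoR
Porion L,PoL
Porion Left,PoL
Po L,PoL
PoL,PoL
Orbitale R,OrR
Orbitale Right,OrR
Or R,OrR
OrR,OrR
Orbitale L,OrL
Orbitale Left,OrL
Or L,OrL
OrL,OrL
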