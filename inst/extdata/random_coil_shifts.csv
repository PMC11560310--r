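resname,nucleus,coil,helix,strand
ALA,HA,4.32,3.94,4.7
ALA,CA,52.5,55.1,51.1
ALA,CB,19,18.62,19.38
ARG,HA,4.34,3.96,4.72
ARG,CA,56,58.6,54.6
ARG,CB,30.9,30.52,31.28
ASN,HA,4.74,4.36,5.12
ASN,CA,53.1,55.7,51.7
ASN,CB,38.9,38.52,39.28
ASP,HA,4.64,4.26,5.02
ASP,CA,54.2,56.8,52.8
ASP,CB,41.1,40.72,41.48
CYS,HA,4.55,4.17,4.93
CYS,CA,58.2,60.8,56.8
CYS,CB,28,27.62,28.38
GLU,HA,4.35,3.97,4.73
GLU,CA,56.6,59.2,55.2
GLU,CB,29.9,29.52,30.28
GLN,HA,4.34,3.96,4.72
GLN,CA,55.7,58.3,54.3
GLN,CB,29.4,29.02,29.78
GLY,HA,3.96,3.58,4.34
GLY,CA,45.1,47.7,43.7
HIS,HA,4.73,4.35,5.11
HIS,CA,55,57.6,53.6
HIS,CB,29,28.62,29.38
ILE,HA,4.17,3.79,4.55
ILE,CA,61.1,63.7,59.7
ILE,CB,38.8,38.42,39.18
LEU,HA,4.34,3.96,4.72
LEU,CA,55.1,57.7,53.7
LEU,CB,42.4,42.02,42.78
LYS,HA,4.32,3.94,4.7
LYS,CA,56.2,58.8,54.8
LYS,CB,33.1,32.72,33.48
MET,HA,4.48,4.1,4.86
MET,CA,55.4,58,54
MET,CB,32.9,32.52,33.28
PHE,HA,4.62,4.24,5
PHE,CA,57.7,60.3,56.3
PHE,CB,39.6,39.22,39.98
PRO,HA,4.42,4.04,4.8
PRO,CA,63.3,65.9,61.9
PRO,CB,32.1,31.72,32.48
SER,HA,4.47,4.09,4.85
SER,CA,58.3,60.9,56.9
SER,CB,63.8,63.42,64.18
THR,HA,4.35,3.97,4.73
THR,CA,61.8,64.4,60.4
THR,CB,69.8,69.42,70.18
TRP,HA,4.66,4.28,5.04
TRP,CA,57.5,60.1,56.1
TRP,CB,29.6,29.22,29.98
TYR,HA,4.55,4.17,4.93
TYR,CA,57.9,60.5,56.5
TYR,CB,38.8,38.42,39.18
VAL,HA,4.12,3.74,4.5
VAL,CA,62.2,64.8,60.8
VAL,CB,32.9,32.52,33.28
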