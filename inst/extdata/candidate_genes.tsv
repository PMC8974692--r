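gene
FLG
CD247
IL1RL1
IL18R1
D2HGDH
PDCD1
KIF1A
KIAA1109
TSLP
WDR36
SLC22A5
IRF1
SLC22A4
HLA-DQB1
HLA-DQB2
HLA-DQA1
HLA-DQA2
BACH2
ZBTB10
IL33
GATA3
MUC5AC
LRRC32
RPS26
SUOX
STAT6
RORA
SMAD3
AAGAB
CLEC16A
DEXI
ORMDL3
GSDMB
PGAP3
MSL1
ZNF652
GNGT2
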