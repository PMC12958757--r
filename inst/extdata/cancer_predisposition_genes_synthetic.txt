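# Illustrative SYNTHETIC cancer-predisposition / DNA damage-response gene
# list for examples and tests. It is a small hand-assembled set of widely
# known predisposition and DNA-repair symbols, NOT the curated list used in
# any particular study; supply your own list for real analyses.
BRCA1
BRCA2
NBN
AXIN2
PRSS1
DIS3L2
CDH1
FANCC
FANCA
FANCL
FANCM
MLH1
MSH2
MSH6
PMS2
ERCC2
ERCC5
BLM
RECQL4
TP53
ATM
CHEK2
PALB2
XRCC3
MRE11
RAD51C
NF1
APC
RB1
VHL
WT1
PTEN
STK11
CDKN2A
SDHB
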