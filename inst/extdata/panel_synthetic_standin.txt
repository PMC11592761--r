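# version: synthetic stand-in v1 (the study's 787-gene list is not published; any one-symbol-per-line list can replace this file)
APC
ATM
ATR
BAP1
BARD1
BLM
BMPR1A
BRCA1
BRCA2
BRIP1
CDC73
CDH1
CDK4
CDKN2A
CHEK2
DDX41
DICER1
EPCAM
EXT1
EXT2
FANCA
FH
FLCN
KCNQ1
KIT
MEN1
MITF
MLH1
MRE11
MSH2
MSH6
MUTYH
NBN
NF1
NF2
PALB2
PDGFRA
PMS2
POLD1
POLE
POLG
PTCH1
PTEN
RAD51C
RAD51D
RB1
RET
SDHA
SDHAF2
SDHB
SDHC
SDHD
SMARCA4
SMARCB1
STK11
SUFU
TP53
TSC1
TSC2
VHL
WRN
WT1
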