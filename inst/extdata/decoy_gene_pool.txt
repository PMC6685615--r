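# Decoy gene-symbol pool for the synthetic-data generator.
# Common human gene symbols outside the RAS superfamily. HRASLS is a
# deliberate near-miss (superstring of HRAS) so substring matching can be
# distinguished from exact matching in tests.
HRASLS
TP53
EGFR
MYC
ACTB
GAPDH
TUBB
VIM
ALB
BRCA1
BRCA2
PTEN
AKT1
AKT2
MTOR
PIK3CA
MAPK1
MAPK3
MAP2K1
RAF1
BRAF
SRC
ABL1
JAK2
STAT3
NFKB1
RELA
JUN
FOS
TP63
MDM2
CDK1
CDK2
CDK4
CDKN1A
CDKN2A
CCND1
CCNE1
RB1
E2F1
H3C1
H4C1
H2AC1
H2BC1
HDAC1
HDAC2
KAT2A
KAT2B
EP300
CREBBP
SETD2
EZH2
SUV39H1
KDM1A
KDM4A
DNMT1
DNMT3A
TET2
SMARCA4
ARID1A
CTCF
YY1
SP1
GATA1
GATA3
FOXO1
FOXO3
SOX2
POU5F1
NANOG
KLF4
NOTCH1
WNT1
CTNNB1
APC
AXIN1
GSK3B
SMAD2
SMAD3
SMAD4
TGFB1
TNF
IL6
IL1B
IFNG
CXCL8
CCL2
TLR4
MYD88
IRAK1
TRAF6
CASP3
CASP8
CASP9
BAX
BCL2
BCL2L1
MCL1
BID
APAF1
CYCS
XIAP
BIRC5
FAS
FADD
RIPK1
RIPK3
MLKL
ATM
ATR
CHEK1
CHEK2
TP53BP1
MRE11
RAD51
XRCC1
PARP1
POLB
PCNA
MCM2
ORC1
CDC6
CDT1
GMNN
WEE1
PLK1
AURKA
AURKB
BUB1
MAD2L1
CENPA
INCENP
KIF11
DYNC1H1
MYH9
MYL6
ACTN1
TLN1
VCL
PXN
ITGB1
ITGA5
FN1
COL1A1
LAMA1
ELN
FBN1
CDH1
CDH2
DSP
PKP2
GJA1
OCLN
CLDN1
TJP1
EZR
RDX
MSN
ANK1
SPTB
ADD1
EPB41
SLC2A1
SLC9A1
ATP1A1
ATP2A2
CACNA1C
KCNQ1
SCN5A
RYR2
PLN
TNNT2
TNNI3
MYBPC3
TTN
DES
LMNA
EMD
SYNE1
NUP98
NUP153
TPR
XPO1
KPNA2
KPNB1
NUTF2
EIF4E
EIF4G1
EIF2S1
RPS6
RPL13A
RPSA
PABPC1
ELAVL1
HNRNPA1
SRSF1
U2AF1
SF3B1
SNRPB
PRPF8
DDX5
DHX9
UPF1
EXOSC10
XRN1
DCP2
LSM1
PAN2
CNOT1
MOV10
AGO2
DICER1
DROSHA
DGCR8
LIN28A
IGF2BP1
YTHDF1
METTL3
WTAP
FTO
ALKBH5
HSPA1A
HSPA8
HSP90AA1
HSPB1
DNAJB1
BAG3
STUB1
UBE2N
UBE2I
UBA1
SKP1
CUL1
FBXW7
BTRC
NEDD4
ITCH
WWP1
SMURF1
USP7
USP14
UCHL1
PSMA1
PSMB5
PSMD1
SQSTM1
MAP1LC3B
BECN1
ATG5
ATG7
ULK1
LAMP1
CTSB
CTSD
TFEB
MITF
PPARG
SREBF1
SCD
FASN
ACACA
CPT1A
ACOX1
HMGCR
LDLR
APOB
APOE
PLIN1
LIPE
PNPLA2
G6PC1
PCK1
FBP1
PFKL
PKM
LDHA
PDHA1
CS
IDH1
IDH2
OGDH
SDHA
FH
MDH2
GOT1
GLUD1
GLS
ASNS
PSAT1
SHMT2
MTHFR
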