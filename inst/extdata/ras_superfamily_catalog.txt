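# RAS-superfamily gene-symbol catalog (default keyword list).
# One symbol per line, order as printed in the source table (row-major).
# Cleaning applied at transcription: the stray trailing period in "RABL5."
# was stripped; the printed duplicate ARHH is kept (deduplicated in the
# normalized view at load time).
AGS1
ARL10B
GBTS1
NY-MEL-1
RAB29
RAB5B
RAN
RHEBL1
RIF
WRCH-2
APMCF1
ARL10C
GEM
R-RAS
RAB2A
RAB5C
RAP1A
RHES
RIG
WTH3
ARD1
ARL11
GES
R-RAS2
RAB2B
RAB5CL
RAP1B
RHO6
RIN
YL8
ARF1
ARL2
GIE1
R-RAS3
RAB30
RAB6A
RAP2A
RHO7
RIS
ARF3
ARL2L1
GIE2
RAB10
RAB31
RAB6B
RAP2B
RHO8
RIT1
ARF4
ARL3
GOV
RAB11A
RAB32
RAB6C
RAP2C
RHOA
RIT2
ARF4L
ARL4
H-RAS
RAB11B
RAB33A
RAB7A
RAR
RHOB
RND1
ARF5
ARL5
H-RASIDX
RAB12
RAB33B
RAB7B
RAR-2
RHOBTB1
RND2
ARF6
ARL6
H-RAY
RAB13
RAB34
RAB7L1
RAR2A
RHOBTB2
RND3
ARFD1
ARL7
H-YPT3
RAB14
RAB35
RAB8A
RAR3
RHOC
RNF46
ARFRP1
ARL8
HRAS
RAB15
RAB36
RAB8B
RARL
RHOD
ROC1
ARFRP2
ARL9
HRAS2
RAB16
RAB37
RAB9A
RASD1
RHOE
ROC2
ARHA
ARLTS1
HRASP
RAB17
RAB38
RAB9B
RASD2
RHOF
RRAD
ARHB
ARP
HSPC137
RAB18
RAB39
RAB9L
RASEF
RHOG
RRP22
ARHC
BBS3
KIR
RAB19
RAB39A
RABL
RASL10A
RHOH
SAR1A
ARHD
CDC42
KRAS2A
RAB19B
RAB39B
RABL2A
RASL10B
RHOH12
SAR1B
ARHE
CDC42HS
KRAS2B
RAB1A
RAB3A
RABL2B
RASL11A
RHOH6
SARA1
ARHF
CDC42L1
KREV-1
RAB1B
RAB3B
RABL3
RASL11B
RHOH9
SARA2
ARHG
CHP
LAK
RAB1C
RAB3C
RABL4
RASL12
RHOHP1
SEC4L
ARHH
CMRD
LOC339231
RAB20
RAB3D
RABL5
RASL7A
RHOI
SMGP21
ARHH
D2-2
LOC401884
RAB21
RAB40A
RABS10
RASL7B
RHOJ
SRPRB
ARHI
DBC2
M-RAS
RAB22A
RAB40B
RAC1
RASL8C
RHON
TC10
ARHJ
DEXRAS
MASRA2
RAB22B
RAB40C
RAC2
RAY
RHOQ
TC10BETA
ARHN
DI-RAS1
MEL
RAB23
RAB41
RAC3
RAYL
RHOT
TC21
ARHQ
DI-RAS2
MIRO-1
RAB24
RAB42
RAD
REM1
RHOT1
TC25
ARHS
E-RAS
MIRO-2
RAB25
RAB43
RAD3D
REM2
RHOT2
TCL
ARHU
FBP
N-RAS
RAB26
RAB45
RAH
REM3
RHOU
TEM2
ARHV
FLJ22595
NKIRAS1
RAB27A
RAB4A
RALA
RERG
RHOV
TRIM23
ARL1
FLJ22655
NKIRAS2
RAB27B
RAB4B
RALB
RHEB1
RIBA
TTF
ARL10A
G25K
NOEY2
RAB28
RAB5A
RAM
RHEB2
RIBB
WRCH-1
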