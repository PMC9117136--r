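gene	lof_mechanism
ACTA2	FALSE
ACTC1	FALSE
APC	TRUE
APOB	FALSE
ATP7B	TRUE
BMPR1A	TRUE
BRCA1	TRUE
BRCA2	TRUE
CACNA1S	FALSE
COL3A1	TRUE
DSC2	TRUE
DSG2	TRUE
DSP	TRUE
FBN1	TRUE
GLA	TRUE
KCNH2	TRUE
KCNQ1	TRUE
LDLR	TRUE
LMNA	TRUE
MEN1	TRUE
MLH1	TRUE
MSH2	TRUE
MSH6	TRUE
MUTYH	TRUE
MYBPC3	TRUE
MYH7	FALSE
MYH11	FALSE
MYL2	FALSE
MYL3	FALSE
NF2	TRUE
OTC	TRUE
PCSK9	FALSE
PKP2	TRUE
PMS2	TRUE
PRKAG2	FALSE
PTEN	TRUE
RB1	TRUE
RET	FALSE
RYR1	FALSE
RYR2	FALSE
SCN5A	TRUE
SDHAF2	TRUE
SDHB	TRUE
SDHC	TRUE
SDHD	TRUE
SMAD3	TRUE
SMAD4	TRUE
STK11	TRUE
TGFBR1	FALSE
TGFBR2	FALSE
TMEM43	FALSE
TNNI3	FALSE
TNNT2	FALSE
TP53	TRUE
TPM1	FALSE
TSC1	TRUE
TSC2	TRUE
VHL	TRUE
WT1	TRUE
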