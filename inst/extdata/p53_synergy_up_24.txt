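# Curated set of 24 p53 target genes synergistically up-regulated
# by combined MDM2 and BET inhibition (gene symbols, one per line).
ANKRA2
ARHGEF3
BBC3
BTG2
CDKN1A
DRAM1
FUCA1
GADD45A
GDF15
IER5
LAPTM5
MDM2
PMAIP1
RAP2B
RRM2B
SERTAD1
SESN2
TGFA
TNFRSF10B
TNFRSF10D
TP53I3
TP53INP1
ZMAT3
ZNF337
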