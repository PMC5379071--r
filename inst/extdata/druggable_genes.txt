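# Illustrative druggable-gene list for breast cancer target nomination:
# kinases, receptors and other actionable genes with approved or
# trial-stage inhibitors. A production analysis should substitute its own
# curated list (e.g. compiled from TARGET/PCT/GDKD/CancerDR/DrugBank).
AKT1
AKT2
AKT3
ARAF
BRAF
BTK
CDK4
CDK6
EGFR
ERBB2
ESR1
FGFR1
FGFR2
FGFR3
FGFR4
HSP90AB1
HSP90B1
IDH1
IDH2
JAK1
JAK2
JAK3
KIT
KRAS
MAP2K1
MET
MTOR
PARP1
PDGFRA
PDGFRB
PIK3CA
PTPN11
RAF1
SF3B1
SRC
TOP2A
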