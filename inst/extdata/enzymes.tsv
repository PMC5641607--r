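name	recognition	cut_offset
# standard REBASE recognition sites; cut_offset = bases 5' of the cut on the top strand
AluI	AGCT	2
EcoRI	GAATTC	1
HaeIII	GGCC	2
RsaI	GTAC	2
TaqI	TCGA	1
HinfI	GANTC	1
MboI	GATC	0
HpaII	CCGG	1
DdeI	CTNAG	1
MseI	TTAA	1
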