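sample	gene	protein_change	vaf	cohort
WHIM9	PIK3CA	p.H1047R	NA	pdx
WHIM9	KRAS	p.A146V	NA	pdx
WHIM16	PIK3CA	p.H1047R	NA	pdx
WHIM24	PIK3CA	p.H1047R	NA	pdx
WHIM18	PIK3CA	p.E545K	NA	pdx
WHIM20	PIK3CA	p.E542K	NA	pdx
WHIM26	SF3B1	p.K700E	NA	pdx
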