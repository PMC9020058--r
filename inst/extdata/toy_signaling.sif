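EGFR	activation	RAS
RAS	activation	RAF
RAF	activation	MEK
MEK	activation	ERK
ERK	activation	MYC
EGFR	activation	PI3K
PI3K	activation	AKT
AKT	activation	MYC
ERK	activation	JUN
JUN	activation	MYC
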