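EGFR	2.5
RAS	1.8
RAF	2.1
MEK	0.2
ERK	1.9
MYC	3.0
PI3K	-0.3
AKT	0.1
JUN	2.2
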