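aa5	aa35	A	C	G	U
T	N	0.70	0.10	0.10	0.10
T	D	0.10	0.10	0.70	0.10
S	N	0.70	0.10	0.10	0.10
S	D	0.10	0.10	0.70	0.10
N	D	0.10	0.35	0.10	0.45
N	S	0.15	0.55	0.10	0.20
N	N	0.10	0.40	0.10	0.40
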