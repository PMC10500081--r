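entity	TT	BG	MT	RS	CC	total
P	30	30	28	5	26	30
I	30	30	30	30	30	30
C	5	0	10	11	8	12
O	6	4	72	71	10	75
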