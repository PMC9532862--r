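group	late	early	total_printed	viable
LN	19.78	4.45	24.23	72.95
LL	29.98	6.89	36.87	60.68
TN	7.29	6.58	13.87	84.63
TL	15.40	16.50	31.90	66.47
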