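allele_name	haplotype	freq_percent
DRB*90101	A1	2.88
DRB*90102	A2	3.37
DRB*90201	A3	15.87
DRB*90202	A4	12.98
DRB*90402	B2	6.73
DRB*90601	B4	4.33
DRB*90602	B5	1.44
DRB*907011	B6	42.79
DRB*90801	B7	5.29
DRB*90901	B11	4.33
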