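feature	subgroup	expr_count	smpl_count
length	VeryLong	0	0
length	Long	1	0
length	MedLong	7	3
length	MedShort	6	3
length	Short	5	0
conservation	High	5	3
conservation	Medium	3	1
conservation	Low	1	1
conservation	NoConsv	2	0
expression	VeryHigh	6	6
expression	High	7	5
expression	Medium	5	4
expression	Low	5	2
expression	VeryLow	0	0
expression	NoExp	0	0
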