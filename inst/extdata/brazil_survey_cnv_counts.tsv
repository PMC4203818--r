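copy_number	total	North	Northeast	Southeast	South
3	67	21	18	14	14
4	16	3	4	7	2
5	3	1	2	0	0
6	1	0	1	0	0
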