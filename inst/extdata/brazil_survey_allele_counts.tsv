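allele	total	North	Northeast	Southeast	South
*1	814	198	192	210	214
*2	438	120	126	97	95
*3	14	3	4	3	4
*4	191	53	50	40	48
*5	94	13	28	28	25
*9	23	5	5	7	6
*10	42	7	9	16	10
*17	114	26	23	38	27
*29	69	11	12	22	24
*34	1	0	1	0	0
*35	53	11	16	15	11
*39	17	7	2	0	8
*41	112	20	41	26	25
*1x2	12	4	3	3	2
*1x3	1	1	0	0	0
*2x2	11	3	2	4	2
*2x5	1	0	1	0	0
*4x2	4	2	0	2	0
*17x2	1	0	0	0	1
*35x2	1	0	1	0	0
Others	27	8	6	5	8
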