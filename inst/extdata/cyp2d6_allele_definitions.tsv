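allele	-1584	31	100	1023	1846	2549	2615	2850	2988	3183	4180	multiplier	activity
*1	C	G	C	C	G	A	A	C	G	G	G	1	normal
*2	G	G	C	C	G	A	A	T	G	G	C	1	normal
*3	C	G	C	C	G	del	A	C	G	G	G	1	none
*4	C	G	T	C	A	A	A	C	G	G	C	1	none
*5	-	-	-	-	-	-	-	-	-	-	-	1	none
*9	C	G	C	C	G	A	del	C	G	G	G	1	reduced
*10	C	G	T	C	G	A	A	C	G	G	C	1	reduced
*17	C	G	C	T	G	A	A	T	G	G	C	1	reduced
*29	C	G	C	C	G	A	A	T	G	A	C	1	reduced
*34	C	G	C	C	G	A	A	T	G	G	G	1	ND
*35	G	A	C	C	G	A	A	T	G	G	C	1	normal
*39	C	G	C	C	G	A	A	C	G	G	C	1	normal
*41	C	G	C	C	G	A	A	T	A	G	C	1	reduced
*1x2	C	G	C	C	G	A	A	C	G	G	G	2	increased
*1x3	C	G	C	C	G	A	A	C	G	G	G	3	increased
*2x2	G	G	C	C	G	A	A	T	G	G	C	2	increased
*2x5	G	G	C	C	G	A	A	T	G	G	C	5	increased
*4x2	C	G	T	C	A	A	A	C	G	G	C	2	none
*17x2	C	G	C	T	G	A	A	T	G	G	C	2	ND
*35x2	G	A	C	C	G	A	A	T	G	G	C	2	increased
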