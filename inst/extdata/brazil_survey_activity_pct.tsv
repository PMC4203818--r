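activity	North	Northeast	Southeast	South
none	14.7	15.9	14.3	15.4
reduced	14.2	17.8	21.4	18.4
normal	68.2	63.2	61.9	64.2
increased	2.9	3.1	2.4	2.0
chromosomes	484	517	509	501
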