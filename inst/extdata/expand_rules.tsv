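name	boundaryElement	carbonylNeighbor	partnerElement	cutOrder	appendElement	appendCharge
acyl_oxygen	C	TRUE	O	1	O	0
acyl_nitrogen	C	TRUE	N	1	O	0
ether_oxygen	C	NA	O	1	O	0
ether_iodine	C	NA	O	1	I	0
amine_carbon	N	NA	C	1	H	0
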