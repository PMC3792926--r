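source_id	property	value	dtype	unit
E1EB7	cty	GZ	string	undefined
E1EB7	qa	E	string	undefined
E1EB7	cc	0	integer	%
D87C9	cty	HK	string	undefined
D87C9	qa	G	string	undefined
D87C9	cc	0	integer	%
B8EF1	cty	HK	string	undefined
B8EF1	qa	G	string	undefined
B8EF1	cc	16	integer	%
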