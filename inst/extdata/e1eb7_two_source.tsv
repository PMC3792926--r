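source_id	property	value	dtype	unit
owner1	cty	GZ	string	undefined
owner1	qa	E	string	undefined
owner1	cc		undefined	undefined
owner2	cty	GZ	string	undefined
owner2	qa		undefined	undefined
owner2	cc	0	integer	%
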