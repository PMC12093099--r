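contiguous_domain	start	end	domain
RuvC-I	1	59	RuvC
Bridge helix	60	93	BH
REC-I	94	456	REC
REC-II	457	502	REC
REC-III	503	713	REC
RuvC-II	714	774	RuvC
HNH	775	908	HNH
RuvC-III	909	1098	RuvC
PI	1099	1368	PI
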