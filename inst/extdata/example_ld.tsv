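snp	proxy	r2
rs000003	rs000103	0.93
rs000003	rs000104	0.85
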