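##track type: step function
##sorted elements: true
##no overlapping elements: true
###end	value
####seqid=chr1; start=0; end=200
38	0.2311
45	0.8485
111	0.1538
121	0.3568
200	0.5452
####seqid=chr2; start=0; end=150
31	0.0012
91	0.3178
108	0.0173
133	0.3416
150	0.3434
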