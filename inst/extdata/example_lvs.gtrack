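##track type: linked valued segments
##edge weights: true
##sorted elements: true
##no overlapping elements: true
###seqid	start	end	value	strand	id	edges
chr1	88	214	0.6017	-	e1	.
chr1	220	240	0.911	-	e2	.
chr1	326	350	0.1754	+	e3	.
chr1	440	572	0.7312	-	e4	.
chr1	586	598	0.0162	+	e5	e6=0.566,e12=0.456
chr1	626	692	0.5861	+	e6	e1=0.662,e9=0.878
chr1	776	960	0.4258	+	e7	e10=0.718
chr2	156	218	0.2105	-	e8	.
chr2	578	686	0.4772	+	e9	e4=0.782,e10=0.962
chr2	696	706	0.7548	+	e10	e8=0.927
chr2	712	736	0.4468	+	e11	e4=0.722
chr2	762	786	0.3712	-	e12	.
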