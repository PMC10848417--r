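chrom	start	end	major_cn	minor_cn
chr15	1	102531392	1	1
chr11	1	135006516	2	1
chr17	1	81195210	1	0
chr3	1	198022430	2	2
chr2	1	243199373	1	1
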