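chr15	77310800	77310822	PEAK1_roi
chr11	68080110	68080132	LRP5_roi
chr17	39723320	39723340	ERBB2_roi
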