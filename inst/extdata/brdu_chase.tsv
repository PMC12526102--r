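# BrdU pulse-chase band intensities, normalized to the 0-h wild-type value
time_h	signal	label
0	1	wild_type
24	0.46	wild_type
0	1	clone_a
24	0.25	clone_a
0	1	clone_b
24	0.44	clone_b
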