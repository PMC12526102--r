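# Circular regions of the human mitochondrial genome (L = 16569)
# 1-based inclusive coordinates; start > end spans the coordinate origin
label	start	end
D-loop	16030	570
oriH	110	441
oriL	5770	5820
TAS	16157	16172
EagI_exclusion	2550	2585
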