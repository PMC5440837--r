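# Additional fragment definitions (tab-separated). Residue ranges are
# author-numbered and inclusive on both ends.
label	chain	start	end
ND2-TM8-plus-loop	A	201	240
GluN1-CTD	B	837	938
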