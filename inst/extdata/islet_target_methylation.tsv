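group	n	mean_methylation_pct
control	16	72
t2d	2	56
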