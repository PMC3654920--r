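# Published counts of tRNA-mapped reads by read size, with the printed
# integer percentages.
length	count	percent_printed
30	16649224	23
31	12343893	17
32	25190160	35
33	18724475	26
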