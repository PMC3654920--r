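# Overall read-mapping and annotation counts from the original mouse-serum
# small-RNA study. "printed" rows are counts published as such; "derived"
# rows were reconstructed from published integer percentages (miRNA = 31% of
# small-RNA reads, repeat = 6% of mapped reads) or as remainders, so that the
# class counts sum exactly to the mapped total.
quantity	count	provenance
preprocessed	196083881	printed
mapped	163078230	printed
small_rna	128703415	printed
tRNA	86343437	printed
miRNA	39898059	derived_from_printed_percent
rRNA_other	2461919	derived_remainder
repeat	9784694	derived_from_printed_percent
unannotated	24590121	derived_remainder
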