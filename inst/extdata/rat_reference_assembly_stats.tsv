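assembly	total_length	ungapped_length	n_scaffolds	scaffold_n50	scaffold_l50	n_contigs	contig_n50	contig_l50
Rnor_6.0	2870182909	2729984219	953	145729302	8	75695	100511	7346
mRatBN7.2	2647915728	2626580772	176	135012528	8	757	29198295	27
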