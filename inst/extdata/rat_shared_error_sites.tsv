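reference	class	count
Rnor_6.0	shared_all36	1310902
mRatBN7.2	shared_all36	143254
mRatBN7.2	shared_snp	33550
mRatBN7.2	shared_indel	95636
mRatBN7.2	shared_hom	117901
mRatBN7.2	shared_het	11285
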