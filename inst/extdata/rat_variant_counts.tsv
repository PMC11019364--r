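population	variant_sites	variants_total	snps	indels	mixed
RatCollection	15804627	19987273	12661110	7313702	12461
HS_progenitors	12418243	16438302	9947112	6479485	11705
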