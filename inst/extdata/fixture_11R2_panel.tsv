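snp_id	position_bp	band	allele_mut	allele_map	anchor
SNP_61A	96000	61A	A	G	distal
SNP_66F	6816000	66F	G	A	
SNP_69C	9696000	69C	C	T	
SNP_75F	17184000	75F	T	C	proximal
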