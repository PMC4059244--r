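##fileformat=VCFv4.2
##source=mosaicmap
##contig=<ID=3L,length=23040000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
3L	1400148	les_62B_missense	G	A	.	.	.
3L	7500001	les_67D_nonsense	C	T	.	.	.
3L	7500204	les_67D_synonymous	G	A	.	.	.
3L	8900001	les_68E_intergenic	G	A	.	.	.
3L	16200753	les_75A_nonsense	G	A	.	.	.
3L	20000001	les_78C_intergenic	C	T	.	.	.
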