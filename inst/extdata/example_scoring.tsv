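#pgs_id=EXAMPLE001
#trait_reported=Example phenotype
#genome_build=GRCh37
rsID	chr_name	chr_position	effect_allele	other_allele	effect_weight
rs1	1	100	A	G	0.1
rs2	1	200	C	T	-0.2
rs3	2	50	G	A	0.3
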