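group_id	isoform_id	gene_id	species
synth1	A.iso1	A.gene	A
synth1	A.iso2	A.gene	A
synth1	B.iso1	B.gene	B
synth1	B.iso2	B.gene	B
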