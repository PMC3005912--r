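group_id	cluster_index	isoform_id	species	is_anchor	anchor_score
SYNE1	1	ENSP00000265368	human	TRUE	1.000000
SYNE1	1	ENSP00000308157	human	FALSE	1.000000
SYNE1	1	ENSP00000356216	human	FALSE	1.000000
SYNE1	1	ENSP00000356220	human	FALSE	1.000000
SYNE1	1	ENSP00000356224	human	FALSE	1.000000
SYNE1	1	ENSP00000390975	human	FALSE	1.000000
SYNE1	1	ENSP00000396024	human	FALSE	1.000000
SYNE1	1	ENSMUSP00000051825	mouse	TRUE	1.000000
SYNE1	2	ENSP00000318783	human	TRUE	1.000000
SYNE1	2	ENSMUSP00000093587	mouse	TRUE	1.000000
SYNE1	3	ENSP00000356225	human	FALSE	
SYNE1	4	ENSMUSP00000039440	mouse	FALSE	
ESR2	1	ENSP00000343925	human	TRUE	1.000000
ESR2	1	ENSMUSP00000075932	mouse	TRUE	1.000000
ESR2	1	ENSMUSP00000106051	mouse	FALSE	1.000000
ESR2	2	ENSP00000335551	human	TRUE	1.000000
ESR2	2	ENSP00000351412	human	TRUE	1.000000
ESR2	3	ENSMUSP00000098849	mouse	FALSE	
AHNAK	1	ENSP00000257247	human	TRUE	1.000000
AHNAK	1	ENSMUSP00000090632	mouse	TRUE	1.000000
AHNAK	2	ENSP00000367263	human	TRUE	1.000000
AHNAK	2	ENSMUSP00000090633	mouse	TRUE	1.000000
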