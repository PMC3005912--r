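gene	cluster	isoform_id	bits
SYNE1	1	ENSMUSP00000051825	11111111111111111
SYNE1	1	ENSP00000265368	11111111111111111
SYNE1	1	ENSP00000308157	11111111111111111
SYNE1	1	ENSP00000356216	11111111111111111
SYNE1	1	ENSP00000356220	11111111111111111
SYNE1	1	ENSP00000356224	11111111111111111
SYNE1	1	ENSP00000390975	11111111111111111
SYNE1	1	ENSP00000396024	11111111111111111
SYNE1	2	ENSMUSP00000093587	11001101011000101
SYNE1	2	ENSP00000318783	11001101011000101
SYNE1	3	ENSP00000356225	11001101011000101
SYNE1	4	ENSMUSP00000039440	10110010100111010
ESR2	1	ENSP00000343925	1111111111111111
ESR2	1	ENSMUSP00000075932	1111111111111111
ESR2	1	ENSMUSP00000106051	1111111111111111
ESR2	2	ENSP00000351412	1111111111111111
ESR2	2	ENSP00000335551	1111111111111111
ESR2	3	ENSMUSP00000098849	1111111111111111
AHNAK	1	ENSP00000257247	111101110
AHNAK	1	ENSMUSP00000090632	111101110
AHNAK	2	ENSP00000367263	111101101
AHNAK	2	ENSMUSP00000090633	011111101
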