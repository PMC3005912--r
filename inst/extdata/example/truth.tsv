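isoform_id	pattern
A.iso1	110
A.iso2	111
B.iso1	110
B.iso2	111
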