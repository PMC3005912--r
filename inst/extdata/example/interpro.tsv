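A.iso1	md5	40	Synth	SIG01
A.iso1	md5	40	Synth	SIG02
A.iso2	md5	60	Synth	SIG01
A.iso2	md5	60	Synth	SIG02
A.iso2	md5	60	Synth	SIG03
B.iso1	md5	40	Synth	SIG01
B.iso1	md5	40	Synth	SIG02
B.iso2	md5	60	Synth	SIG01
B.iso2	md5	60	Synth	SIG02
B.iso2	md5	60	Synth	SIG03
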