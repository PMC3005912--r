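>A.iso1
DEARLFWYAIFIEHPCHFCCRIKPAVNQIIQPVVKQGKQE
>A.iso2
DEARLFWYAIFIEHPCHFCCRIKPAVNQIIQPVVKQGKQEYIQFRMWFQAYYGQKQGELT
>B.iso1
DEARLFWYAIFIEHPCHFCCRIKPAVNQIIQPVVKQGKQE
>B.iso2
DEARLFWYAIFIEHPCHFCCRIKPAVNQIIQPVVKQGKQEYIQFRMWFQAYYGQKQGELT
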