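path:map00010	md:M00001
path:map00020	md:M00002
path:map01100	md:M00001
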