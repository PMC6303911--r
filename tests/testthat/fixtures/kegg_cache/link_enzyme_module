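md:M00001	ec:1.1.1.1
md:M00002	ec:4.2.1.2
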