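path:map00010	ec:1.1.1.1
path:map00010	ec:2.7.1.1
path:map00020	ec:4.2.1.2
path:map01100	ec:1.1.1.1
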