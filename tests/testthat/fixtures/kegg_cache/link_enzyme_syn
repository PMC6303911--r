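syn:g1	ec:1.1.1.1
syn:g2	ec:1.1.1.1
syn:g3	ec:4.2.1.2
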