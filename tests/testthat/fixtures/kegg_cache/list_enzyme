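ec:1.1.1.1	alcohol dehydrogenase
ec:2.7.1.1	hexokinase
ec:4.2.1.2	fumarate hydratase
ec:6.3.1.9	synthetic ligase
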