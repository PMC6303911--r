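cpd:C00001	H2O
cpd:C00002	ATP
cpd:C00003	pyruvate
cpd:C00004	NADH
cpd:C00005	fumarate
cpd:C00006	malate
cpd:C00007	orphan compound
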