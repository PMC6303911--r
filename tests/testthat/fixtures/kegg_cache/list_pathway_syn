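path:syn00010	Glycolysis / Gluconeogenesis - synthetica
path:syn00020	Citrate cycle (TCA cycle) - synthetica
path:syn01100	Metabolic pathways - synthetica
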