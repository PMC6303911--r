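ec:1.1.1.1	rn:R00001
ec:1.1.1.1	rn:R00002
ec:2.7.1.1	rn:R00003
ec:4.2.1.2	rn:R00004
ec:6.3.1.9	rn:R00005
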