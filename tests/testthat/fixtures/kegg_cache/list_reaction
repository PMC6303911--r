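rn:R00001	reaction one
rn:R00002	reaction two
rn:R00003	reaction three
rn:R00004	reaction four
rn:R00005	reaction five
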