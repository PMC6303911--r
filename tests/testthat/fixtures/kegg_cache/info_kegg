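kegg             Kyoto Encyclopedia of Genes and Genomes
kegg             Release 110.0+/05-24, May 24
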