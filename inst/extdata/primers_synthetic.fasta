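>wga_primer_synthetic
GTCAGTACGGCTTAAGCCTGAGTCCAGTTCAGGACCTAGGATACGCGT
>seq_adapter_synthetic
CTAGGTTGACCAGCTAAGGTCGATCCTGAACGTTAGCAGTCCATGCAA
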