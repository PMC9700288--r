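>adapter_top_synthetic
TTCTAAACTAACGGTGTCGCGCGAGCCATGCG
>adapter_bottom_synthetic
ACCGCTTGCCAGGTGCTTCTGTGATA
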