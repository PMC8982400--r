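# Two contemporary populations A and B, both derived from an unsampled
# ancestral population C, with migration among A and B.
# adjacency[j,i]: '*' migration j->i, 'd' divergence (j derived, i
# ancestral), 'D' both, '0' none; rows comma-separated.
populations = A B C
samples = 10 10 0
adjacency = -*d,*-d,00-
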