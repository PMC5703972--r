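GGTGGT
TGGTGG
GTGGTG
GGGTGG
GGTGTG
TGTGGG
GTGTGG
TGGGTG
GGTGGG
TGGTGT
GTGGGT
TGTGGT
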