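# Published HBB amplicon assay oligonucleotides, stored verbatim.
# The source table lists FP2 and RP1 with the identical sequence; both are
# kept as printed and the collision is flagged below instead of guessing the
# intended primer.
FP1: cacttagacctcaccctgtg
FP2: tatgggacgcttgatgttttct
RP1: tatgggacgcttgatgttttct
RP2: ctctgcctattggtctattttccca
ssODN: TCAGGGCAGAGCCATCTATTGCTTACATTTGCTTCTGACACAACTGTGTTCACTAGCAACCTCAAACAGACACCATGGTGCACCTGACTCCTGTAGAGAAGTCTGCGGTTACTGCCCTGTGGGGCAAGGTGAACGTGGATGAAGTTGGTGGTGAGGCCCTGGGCAGGT
fp2_rp1_identical: true
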