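>GENE1_tx|cds
ATGTGCATAATGGTCAGCCGTCGCATGAGTCATCTGCGCTACTTTGACTTTAGCAGCCCTATGGACGCACCCCCTCATTT
AGGGCCTATCATGTTATCAAGGTCAACTCATTCAGTTAGATGTCGAGAACGATCTCCAGTTCTCGGTACAATGGCTCCTG
AGCGACGTCCGAGTAGCGGGATTAGTCGGGCATCGTTTTTACTCGTAGTGGGGAAGGAGGTAGTGCTGCCACCAAAACTT
CCACTTAACACCCGGGCCGGTTTAAGCCCCCCCAATCGGCCCTATGGAGCCTCAATCAAGTGCGGAATAACGAGCCGATT
TGGAAGTAAAGGCGCTGATATACGAGAAGCGTACTGGCGGAGCGAGAGCTATCATACTACAAGGACCGTTATCATTCGGT
CCCATACGTCCACAGCCCCGCCGACACCAACCCCCAGATCCATTAACTTAACATGGAGTGCCCACCGTGGGCACGTAAGC
GTTTCATCAAGGCTCTTGGATTTCGGCCTTCGACATCCGATAGCGTCCCTTTTGGCAGTCTTTAGATTACTATGTTTGAG
ATTCATCGCTAACACTGGATCCACAGCGAACCGATACAGCGATGCTAACGCCAAATGCTCTCTCGATAACTGGTCCGTGT
CGGGGGTCAGGTGGGTAACAATTCAAAATCAGTGTTTTCCGTCCTACACTAATTTCTACCTTTCTAAGCAGCGCCACATC
CGCGCCCCGTGGAACACTAACTGCGGAAGGAACTTCTTGCCGCGCCAATCTAGCGAGGGAGACGTCGGACGATACTTTCT
ATCCGTTTCCACTTCACTCCTCATACAGGTACGGCTTCCCGACTAA
>GENE1_tx|junction1|donor
GTCCTGGCCCCTTTCTTTTACAAGGGCCTC
>GENE1_tx|junction1|acceptor
GTCAGGCTATCTAATGTGCCTTACCACAAG
>GENE1_tx|junction2|donor
GTAGAGCAGGTCACATTTAAGGTACCTCCA
>GENE1_tx|junction2|acceptor
ACTGAAACGACTTGAACCTACGGAAAAAAG
>GENE1_tx|junction3|donor
GTTAGGAGGGACGCTTCCTCTGAGACCATT
>GENE1_tx|junction3|acceptor
GATGAGCATCAAAAGGGGAGCACTCACAAG
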