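>hY1 synthetic stand-in for human hY1 (112 nt, 10-nt terminal stem); not the NCBI sequence
GCTACATGACTGCGCAGAATTGTACCAAAAGTTTGTACCCTGTGTGCTAGCACTCAACCTTCCGCTTTCTGTGAGACGACCCCCTGAATGTCCCCCAAGAAGGTCATGTAGC
>hY3 synthetic stand-in for human hY3 (101 nt, 10-nt terminal stem); not the NCBI sequence
CTAACAGACATTTGTAGGCGTTGAGGTGATGCAGGAAACCCAGCGAGCTATTGAAAGTTGGTCAAGTAGCGAAATTGAGAACTGAACTTGGTGTCTGTTAG
>hY4 synthetic stand-in for human hY4 (93 nt, 10-nt terminal stem); not the NCBI sequence
GAATACTGTCTCAGTGATATCGATAAATCTCCAAGCGGTATGCGGGATAGTTGGGGTTATGGGATACAATCTACTGGACTGGTGACAGTATTC
>hY5 synthetic stand-in for human hY5 (83 nt, 10-nt terminal stem); not the NCBI sequence
AGGGACCAGCCTCATCAGGACGGAATCAACCCGATCGGTATCAGGGTAGCTAACCGAAGCGCGTGCTTTTTCTGCTGGTCCCT
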