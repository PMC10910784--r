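>CentBd_synthetic synthetic stand-in consensus (156 bp)
AAAAACTGGAGGAGATACTCAGCTACCGGGTATGAGGAAGTTTAATTAATGTGCGAATACAAGCGACTTGTAATAAGGTATTACGAGCAAACTTTATCGAAGTTCTTGATTATTTCCAACGAACACAAACGTTCTGACGCTTATAGAGCGTCTGGT
>CentBs_synthetic synthetic stand-in consensus (157 bp; 19 SNPs + 1 bp insertion vs CentBd_synthetic)
AAAAAATGGAGGATATACTCACCTACCGGATATGAGGTAGTTTAACTAATGTGAGAATACATGCGACTTCTAATAAGATATATACGTGCAAACTCTATCGAAATTCTTGAGTATTTCCGACGAACAAAAACGTTTTGACGCTCATAGAGCATCTGGT
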