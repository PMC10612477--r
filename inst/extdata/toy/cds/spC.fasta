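>fam001_spC
GATTCACTGAGTAAGCGGTTCTACATGACAAACTCTGTCAGCGCCGTCCTAGCCGGCGTA
GTTTGTAGTCACTTTCCGAGGATTTTCCGGCCTCTGCAAACCGGTGTTATTGCCAGTCAC
GCCTTCCAACGGCAGCGAAGGCCTACCGGCTGTAACGGTGCAGTTAAGTCTGCACAGTTG
CGCCTAAACGAGCTTTCACAACATTCGAGATTAATGGATCGTGTCATAAGGGATCCGGAA
TCGTTACTTGACATATACTCTAAACGTCTAGATATACACCCCAGGCGGTGTAAGCCTCCG
GAAGTCTTCAAGCATTCACATACCAAGGAACTTTATCAGCTCCGGACGACTCTGTGGCAA
TACTCGGCACCGAGGAGCCTTATTGTGCGGCAATTGGTGCGTCCACGTGTACTTGCAACA
CAATCGTCGGCACGAGCTAAATGCGGACTCTAA
>fam002_spC
GCCGCGTTGCAGCAGGGTACTAGCGTTGCAGATTTGGTTGTGACCGGCTTGACCGACTAC
ACGGACGAACGCTACCCCTGCATGTGGATACAACGCGCTCGCTCTATACAGACGTCTCCA
GCAGGGTCACACAGATACCTGACTTGTAAGCTCTGCCTAGTCGTACATTGCACATGTGTG
ACATTGCCCAAACATGTATGGAAGTTAGTCGTGTTAAGCCTTAAGAACGGTCTTTTGCTA
GGTAAGCCCTACACGCTCCGTAATCTTGCGATCTACGTCCGGTGTGCAGTGCCCGAAGGT
CAAGAGAAAACTGGATACGGCCGTCCCCTATGTCGTTCAGCGGCAGATACATGCCTGGGT
TCCGAGAAATCTGACGACTGGCACGCCCGACCACTCCTCTATGTGGTGGTATCAATGGCC
GACCCGATATTGCGGTCGGCACTTCGAATATAA
>fam003_spC
TCACGCAGGACCACGGGCAAGCTTTACTCATTTAGACTCTCGACTCACTCTCGATGCCAG
CCGCTCAACTGGCGAGCAATGGTAGTCCTAACCTATTACGTTAGGCCAACACTACCTGCC
TCTATATCAGCCTTAGTGGCTCGGAAGGTGATACCCGTAGGGGCAATCATGGTTCCGAGG
AGTGCCTTTACGCGCAAGAGGCGGCCCACGATAAGCGGTCAAGCGGCAATCGGGTACAGT
CAGCTCACGTTTAAGTCAGGGCTTATCCTGATGAAAAGCGAGGGTGCGTCCACGAGAGCT
ATATTGGAGGTGATACTGGCAAGGAGCCTGCTAAGAAATTCCGTACGGTCGCGCTACCGG
CTAAGGGGTAATGTTATTTCAAGCTTCGACGGGGTAGGGGAGCCAAGCTGTGCCTCCGCC
AGCTTGTTAAGTTTTATCGGAGAATATTTCTAA
>fam004_spC
TGGCAGCAGGCGTTTTGTAGGGAGAAGTGTAGTTGTCGTCTCTATGCGTCCAAAGTAGAT
ATAAGGTGGCTCAAAGGATATAGCTCCCGAGGTTCGGGTGGGATAGCTTTTTGGGCTACG
ATGTTAGTTTACGAGCGGCCCTGGTTGCAAGTTGCTGATCATGTTCGATATAGAGTAGTT
AGCAGAAGCACACAGCGGAAAACACCCCCCGCCCACGGAAGAAGGTATCGAGTCCCAATC
TGCACTAAGAGACCAGTAAAGGCGCCGAGCCTCGAGAAGTGTAGTCCGTCAATCCCTGGG
AGCCTATACTCGCACCCGAGTATTGACAACTGGTCAGCCAATCTAAGTAGAATCTCGCCA
GAGCTCCGAATGTTCATCTATTGTCAGCAAAACCTCCCTCGTGTCCAGTACGGCTTAGAG
CAACGCGAACGCAAGAGGCCAAATGAAAGGTAA
>fam005_spC
CGCCTGCTGAAAGTTTTGAGTGCGAGTTGGATTCCAGGACCTCCACGCGATAGTTTTCTA
CATCTTAGTGTGTCCAGCAAACCCGGCCACACTGTACTTCTAGAGTCAGTAAAAGACTGG
CCGGTTGATGATAAAGTAACAGCCTACTCAAGCCGACTAGCGGATTTAAATACCAGCCGA
GTTACTACGAGTGCGCAGGTGGTCATCTTTAGACTCCACTACATCCACGTAATATTGCAG
CAGTACCTTGTGGCTGCACCGATTTCAGCAATACGTACCGCCTTAGGACCATCCCGGTTA
ACCGTTGATCGCCTTCCTTCCTATACGATTACTTATGGCGGCGTCCATTTTCTTTTGGTA
ACGTATACGCGCGGCCACCACCTGCCAAAATTTCTGGATTGTGCCACGGCATTCTCATCT
ATCAACAGTTTTCGCACACGACGACAGGTATAA
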