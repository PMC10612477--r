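>fam001_spB
GATTCACTAAGTAAGCGGTTCTATATGACCAACTCTGTAAGCGCCGTTCTAGCCGTCGTA
GTTTGTAGTCACTTCCCGAGCATTTTCCGGGCGCTGCAAGCGAGTGTCATTGCCAGTCAC
ACCTGCCAAAGGCAGAGAAGGCCCACCGGTTGTAACGGTGCAGCTAAGTCTGCACAATTG
CGGCTAAACGAGCTTTCACTACACTCGAGACTAATGGACCGTGTTATAAGGGACCCGGAA
TCGTTACTTGACATATACTCTAAACGTCTTGATATACACCCCAGGTGGTGTAAGCCTCCA
GATGTCTTCAAGCATTCACATACCAAGGAACTTTATCAGCTCCGGACAACTCTGCGGCAA
TACTCGGCACCGAGGAGCCTCATAGTACGGCAATTGGTGCGACCACGTGTACTTGCAACA
CAATCGTCAGCACGAGCTAAATGCGGACGCTAA
>fam002_spB
GCCGCGTTGGAGCAGGGTTCTAGCTTTGCGGATTTGGTTGTGACCGGCTTGACCGACTAT
ACAGACGAACGCTATCCCTGCATGTGGGTACAACGGGCTCGCTTTATCCAGACCTCTCCA
GCAGGGTCACACAGATACCTGACTTGTAAGCTTTGTTTGGTCGTACATTGCACATGTGTG
ACATTGCCCAAACGAGTATGGAGGTTAGTCGTGTTAAGCCTCAAGAACGGTCTTTTGCTA
GGTAAGCCCTACACACTCCCTAACCTTGCTATCTACGTCTGGTGTGCAGTGCACGAAGGC
CAAGAGAAAACTGGGTCTGGCCGTCCACTGTTTCGCTCCGCGGCAGATACATGCTTAGGT
TCTGGGAATTCTGTCGCCTGGCACGCCCGTCCACTGCTGTGTGTGGTGGTATCAATGGCC
GACCCTATATTGCGATCGGCACTTCGAATCTAA
>fam003_spB
TCACGCAGGCCCCCGGGCAAGCTCTATTCATTTAGACTCTCGACACACTCACGATGTCAG
CCGCTAAACTGGCGCGCAATGGTAGTCCTAACCTATTACATTAGGCCGACACTACTTGTC
TCTATATTTGCACTAGTGGCTCGAAAGGTGATACCCGTAGGGGCAATTATGGTACCGAGG
AGTGCCTTTACGCGCAAGAAGCGTCCCACGATGAGCGGCCAGGCGGCAATCGGTTACAGT
AAGCTCACATTCAAGTCTGGGCTTATCCTAATGAAAAGCGAGGGTGCGTCCACCAGAGCT
ATATTAGACGTGATACTGGCAAGGAGCCTACTAAGAAATTCCGTACGGTCCCGCTACGGG
CTAAGGGGCAATGTCATATCAAGCTTCGATGGGGTAGGGGAGCCAAGCTGTGCCTCCGCC
AGCTTGTTAAGTTTTATCGGTGAATATTTCTAA
>fam004_spB
AGGCAACAGGCGTTTTGTAGGGAGAAGGGCCGGTGTCGTCTCTACGCGTCCAAAGTTGAC
ATACGTTGGTTAAAAGGGAATAGCTCCCCAGGTTGGGGTGGCATAGCCTTTTGGGCAACG
ATGGTAGTTTATCAGCGGCCCTGGTTGCAAGTTGCTGACCATGTTCGATATCGAGTAGTT
AGTAGAAGCCCACAACGGAAAACGCCCCCCGCCCACGGAAGAAGGTATCGACTCCCAATC
TGCACTAAAAGGCCCGTAAAGGCATCTAGCCTCGAGAAGTGTAGTCCGTCAATTCCTGGC
AGCTTATACTCGCACCTGAGTATACACAACTGGTCCGCCAACCTAAGTAGAATCTCGCCA
GAGCTGCGGATGTCCATTTATTGTCAGCAAAACCTCCCTCGTGTCCACTACGGGTTAGAG
CAACGAGAGCGCAAGAAGCCTAATGAAAGGTAA
>fam005_spB
CGCCTGCTGAAAGTTTTGAGTGTGAGTGCGACTCCAGGTCCTCCCCGCGATAGTTTTCTA
CTACTAAGTGTGTCAAGCAGACGCGGCCACTCTGTACTTCTTGAGTCAGTAAAAGGCTGG
CCGGTTGATGTTAAAGTAAAAGCCTACTCAAACCGACTAGCGAATTTACATACCGGCCGA
GTTACTACGAGTGCGCAAGCGGCCGTCTTTAGACTCCACCAAATCCACCTAATATTGCAG
CAGTACCTTGTGGCTGCACCAATTTCAGCACTATGTACCGCCCCAGGACCATCCCGGTTA
ACCGATGATCGCCTTCCTTCCCATACGAGTCCTTATGGCGGCGTCCATTTTCTTTTAGTA
GGGTATACGCGCGGCCATCGCCTGCCAAAACTTCTGGATTGTGCCACAGCATTCTCATCT
ATCACCAGTCCTCGCAATCGAAGACGGGTATAA
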