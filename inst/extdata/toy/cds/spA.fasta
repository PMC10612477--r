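>fam001_spA
GATTCACTAAGGAAGAGACTCTATATGACCAACTCTGTGACGACCGTCCTAGCCGGCGTA
GTTTGTAGCCATTTTCCGAAGACTTTCCGTGCGCTGGAAACCGGTGTCATTGCCAGTCAC
GCTTTCCAAAGGCAAAGAAGGCTTACCGGTTGCAACGGTGCAGTTAAGTCTGCACAGTTA
CGCCTAAACGAGCTTTCACTGCACTCGAGATTAATGGATTGCGTCATAAGGGATCCGGAA
TCGTTACTTGACATATACTCCAAACGTCTAGATGTACACCCCAGGTGGTGCAAGCCTCCG
GATGTCTTCAAACATTCACATACCAAGGAACTTTATCAGCTCCGTACCACCTTGCGCCAA
TATTGGGTACCGAGGAGCCTTATAGTGCGGCAATTGGTGCGGCCACGTGTCCTTGCAACA
CAATCGTCGGCACGAGCAAAATGCGGTCTCTAA
>fam002_spA
GCCGCGTTGCAGCAGGGTACTAGCTTTGCAGATTTGGTTGTGACCGGCTTGACCGACAAC
ACGGACGAACGCTACCCCTGCATGTGGGTACATCGGGCTCGCATCATACAGACGTCACCA
GCAGGGTCACACAGATACCTAACTTGTAAGCTCTGTTTGGTCGTACATTGCACATGTGTG
ACACTGCCCAAACGGGTATGGAAGTTAGTCGTGTTGAGCCTTAAGAACGGTCTCTTGTTA
GGCAAGCCCTATACTCTCCCTAACTTTGCTATCTACGTCTGGTGTGCAGTGCCCGAAGGT
CAAGAGAAAACTGGGTTTGGCCGTCCATTGTTTCGCTCGGCGGCAGATACATGCCTAGGT
TCCGGAAACTCTGATGACTGGCACGCCCGTCCGCCTCTCTATGTGGTGGTATCAATGGCC
GACCCCATCTTGCGATCGGCACTTCGTATATAA
>fam003_spA
TCACGCAGGACCCCGGGCAAGCTTTATTCCTTTCGACTCTCTACCCACTCTCGATGCCAG
CCATTGAACTGGCGGGCAATGGTAGTCCTAACATATTACGTTAGGCCAACACTACTTGCG
TCAATATCTGCCTTAGTGGCTCGGAAGGTGATACCGGTAGGGGCAATTATGGTCCCGAGG
AGTGCCTTTGCGCGCAAGAAGCGTCCCACGATGAGCGGCCAGGCGGCCATCGGTTACAGT
AAGCTCACCATCAAGTCAGGGCTTATCCTTATGAATAGCGAGGGTGCGTCTACGAGAGCC
ATATTGGACGTGATACTAGCAAGGAGCCTGCTAAGTAATTCCGTACGGTCACGTTACCGG
CTAAGGGGCAACGTTATATCAAGCTTTGATGGCGTAGGGGAGCCAAGCTGTGCCTCCGCC
AGCTTGTTGAGTTTTATTGGTGAATATTTCTAA
>fam004_spA
AGGCAACAGGCTTTTTGTAGGGGGAAGCGCAGGGGTCGTTTCTATGCGTTCAAAGTCGAT
ATAAGGTGGCTAAAAGGGAATAGTTCCACAGGATCAGGTGGGATAGCTTTTTGGGCTACT
ATGCTAGTTTATGAACGGCCATGGTTGCAAGTTACTGACCATATTCGATATGGAGTAGTT
AGCAGAAGTCCACAACGCAAAACACCCCCCGCCCACGGAAGAAGGTATCGACTCCCAATT
TGCACTAAAAAACCTGTAAAGGCACCGAGCCTCGAGAAGTGTAGTCCGTCAATTCCTGGG
AGCTTATACTCGCACCGAGGTATTGACAACTGGTCCGCAAATCTAAGTAGAATCTCGCCG
GAGCTCCGAATGTCCATCTATTGTCAACAGAACCTCCCTCGTGTCCACTACGGTTTAGAG
CAACGCGAACGCAAGGAGCCTAATGAAAGGTAA
>fam005_spA
CGCCTGCTGAAAGTTTTGAGTGTGAGTGCGAGTCCAGGTCCTCCACGCAATAGTTTTCTA
CAACTTAGTGTGTCAAGCCGACCCGGCCACTCTGTACCTCTAGATTCAGTAAAAGTCTGG
CCGGTTGCTGATAAAGTAAAAGCCTACTCAAGCCGACTGGCGTTTTTAAGTACCAGCCGA
GTTGCTACGAGTGCGCAAGTCGCCGTCTTTAGACTCCACGTCATCCATCTATTATTGCAG
CAGTACCTTGTGGCTGCACCGATTTCAGCAATACGTACCGCCCTAGGACCATCCCGGTTA
ACCGCTGATCGCCTTTCTTCCTATACGAGTCCTTATGGCGGCGTCCATTTTCTTTTAGTA
ACGTGTACGCGCGGCCATCGCCTGCCATACCTTCTGGATTATGCCACGGCATTCTCATCT
ATCACCAGTGTTCGCGCTCGACGACAGGTATAA
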