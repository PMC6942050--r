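>rdna_synthetic|synthetic|NA
CTGCGCAACATGAAGCAGAGGATACCGACTTCGCCGACTGAGCGATGTCGTTAACAGTCCCTCACGCGGCTAATGCCCAG
CAGAGAAGCTTTCAGAATGGGATAAAGTTACGAGCAGGTTCGCCAAAGTATCTTAGTAAGCTCATTCTCAAAATTTGCAC
AAGTGCTCCCCATTGATAATGAGTCCAAATGGACTCTCACTACGTGTTTCGCACGTACGCTACATTTTCCCGCCTGGCCG
AGCTTGGGTGACTATTGAGAGAAGTTATTTTTAAGACTTGGAGAAGCGGGGTTACCAGACACAACCCTAGGGGTGTAGTG
ACATTCTTAGTTGCCAGAAGGGCTACAAAAGAGCCTTAAGTCACAGGCTTTATTCGCATACAACTACCAAGAGATGGAGT
CCAAGACCTTCAGGTTCGTTAGTTTGGAGCAGTTAGAATGATGCGTTACTGATGATGTCGCTAGGCAGTGACGTGGGGCA
AGTCGGTGTGCTTCAGTCGAGAAGAAGGACAACGACCGCTGAGCCGTATGATTGGACACGTTAGTTCACAGTCGGCTTCG
GAAAGTAAGGTTGAGCACAGTGCATATCTCCGTGACCCCGAGACCAAGGATTCCCGGTAAAGTCACATTGAATGCGCATG
CTGATTGATAGCATGTACCGTCGCATGGTGTACGCTGTAATAAGGGAGTCGTCCTGGAGTCTCGACCCATTCGGGTTCAT
ACGCGCAGAGCTATGAGTTAATGCGATGAGACCAAGTTGGTCGTGGGCAGAACGTTGGCTCCACTGTACGGGTAACCCGA
GGACATTAGTACCTATGGCGAATCGTGTGTTCGGTGAAGTACTAAAGAACAAGGGAGGATCTAATTAAGTCCTTTACGTA
AGAAGTGCACTTAAGTAATTAGACATATATGTGCAAAATGTATTGGCGTACGTGTGTGACCCGCTGACCGGACCGTAGCC
GTGCACCACCATGATTGAGATTCGTCCTGGAGATGGAATTAAAACAAGAGCCCAAGGGGGTATATCGGGGAAACGATAGT
AGCCCAATGGGCCAACAGCTCTCCCCTTAGCTTCATAGATTTAGACTAGTGACAGGGCAAGCGCAGGCCGCCCAAACAAC
TACTCGCGAGAAGATCAAGGGGATGGTACGCCCTGTAGCGGCCCGGAATAGCACGATTGAACTACCTGAGTCAATTGGCT
TAATTCTACGTTAAGTGGACTGCCACCAATCGCAACCCGTGTCAGGTTATCAGCCTAGCTTTAACCGTTGGACTACAAGG
CTACATAGGGAGGGTGGTCCAGATTCGGCCAGATCATCGGCTGGCTATGCCGTCAGAAAAAGTCTATAAGGCCCGCGGGT
GAGATCCATATGCTGTTTGGGGACTAGAGGGGATACCTTCATACTAACTCCTGTAGTTCAACCGTGTTTTGTTCTGCATG
TGTTTGTCCCAGCTATCCCTTTGTACATGATACTAAGATTTCCAGCATGGTGCGACCTAGCAGCAGCATCGAATTAGTCA
ATATTAATCTGCCTAGGTACCCGTTCGAGGGGAGTGTTAACACGCCAGTTTCCCATTACTCATGCCCTTACACGTGTTTT
TTAGTAAAATGTGCTTCCTATTGCGTCTCGTTCAATAGTGACAACTTAGAGATTTTTATTTCAGCGGTATGGTCGGCTTG
AGTGAATGAACCAGCTTACTTAGCCGAGACGAGCATCTTGTAGCGATATGGTCGCGACGCCGAAATAGGAAACATGGACG
CGTTTCGTCCTCATTGGGCCATTAACTATGGGGCTTCATCCCACCAGCTTGGAACTCAGGTTGTCTTGGGAATTCACTGA
ACAAACACAGGGGCTCTAGCAGTTCTTATACCCTCTGGACCCGTGTTAAGCCCACCTCTTGTCCTCCACAGATTCATCTC
CAGGCGATCCACGTTATACATGACTTCTGACCACGTCATTGTATCTAGAGTCCCGGAGCCCCGGATTGGATTCATATTTC
GCGACAAGTGAGAAATCGTTGGGTAATACATTCCGTTTACATAGGGCGGGTACGTCCCTCGCGTAAATTAACCACAGAGC
TACGGGAGGCAAGACCGCCGCCCGAGTTTATGGTTGAACGATTTCAACGGTACATGGCAGGTAGATTCCGCCATCTATTC
CTGCCTTTTAGTAGGGAGATATAGAAAGAATTAGGTCCCCAAGCGATCTCGCACAATAGCGACGGATGTGACCTGAACTA
CACGAATTGCGCCCATTAGGTATGCCGTGGGTCCGACAGAAATCCATCTCCCGTTCCGGCATTGGACGGCCTGTGACTAG
CACTTAGTTCGAAGATATTATGCCGTGCAAAAGTATTTTGGCAGCGATGAGAGTTCACTAACCTTGAATTTGTACTGTTA
AGGCTTTGTTGGGCTTGAGAGACCATGGCTTCCTGAGACCGTCTTTGGTAAGTTACTCGTGGGGTGGGGGTCCTTAGATC
CTCGGTTCTGCTCAACCAAGATAGTTGCAATTAATACCTAGCACGACGCATCTGGGCCCACTGTTTGGTGCAATGCGGCT
CACCGGGATTGGCAACTCCCTTTCTGGAAGTCCGAGGCGCACGGGTGTAGAGGCGCGTCCCCTCATAAGAAAATCGCAAT
AAGATTATTAATGCCAACTCCTAACGGACCGAGCGGCCAAGGGAGTAGGCAAATCCTCCGCAGGACCCTGCTCTCCTCTG
AGGGTGCTCCGGCTCGAACAGCTATGGCTTAGGTACTCAGGGGCAACTGGAACTAGGAAACAATCCTTTTATGTGTCACG
CCCAGCATCACTACGCAGCGGACCTGTTTTTCCATGTAGGGCTGTTCGAGATGGTTGTGCTTGCGGCACTCTCATAAATG
TTTGTGGCGAGCCGCTAGGACGTTGGCTAGACGTCCTTTTCGCAATATTCCACTGCGGCCACGGCTTACATGAGGGTGCT
TAGAAGACCCTGAGGGGCCTCCACACGAGTTTTTGTCTGGATAGAATGCACCGTCCTAAGGGAAAAGAGACGACACACTT
AGTGTGGCCTCTTACTTTCCGTCGTCGTAATCGCGGCACCTAATGCACATCTTAATGACAGATGCGCTACACTCTGGATG
GGTACAGGGTTCTCGGATCTGATATTGGACCGGAGTGTTAGTACGCCGGTTGTCGGACAGTAGATAATGTCCCCACCACT
AGGCACGCCAGGTCCCGTCAGTCCGGTGTATCTCTCAGGAGGCGTAAAGTTGGGTGAATCCGCACAACTATTTCACCCGT
AGCGCGATACATATGAACGGCGAGTCTGCGGGCTTGGACTGGGGACTAGTTGCCCATGCACAGTATGCTTCCACATGGAA
GCGAAACGTAAGATCGCGGGATCCGAGTTGTACAGAGTCTCTAGAGTAACAAGGGGCGTTTGTGTAACAGAAAAACTATA
CCACCCGAGGAATCCCACGCACAGATTCCGACCTGGACGGAAATTATGGTCTAGGGACGATTGAAAATAACGTTTAAGGG
ATCCATAGATACATGACGCAAGTCCGCAGCATCACCCGGCGTAAAAGTCGCTACCTAAAAGCCTAGCATTAATTACATTT
CTAAGCTATCGGGACGCGGTTCATACTCAGTTTTCGTCACCAGAACCATAACCAGGACAGACCGACTAGCGGTGTGCTCA
ATACAATGGAATATATATCTGTTAATCCGAACAAATGTGATTCATCTTCGGTTTGTCGAGCTCTTCACACCAAGCATTTG
AGACCACCGTAGATGTACGACCGTGGGGGATTTCGAACCAGTGGGGGAAATCACTTTGAGATGTGGACTCCCTGAACTAT
CCTTAAGTGCGGGTGGCCAACATTTCTTTTAAATTCTGGAGATCCTGAGCGACTTATTCACGTTCGGTAGTGAAGGACTG
CAGGACTTTTTGTAGGAAAATCCTGAGACAGGAGGTTCTTTCGCGAATCGCATTCGGCTTCCCAGCCCACTTTGGTGCTC
AGAATGCAACAGATGTGTTTCGCTGACTTTGTACAGCCGTCAGTATCTCTTCATACGGCCGTTCGCTATTGCATGCTGTG
CCGGCTGGACATTTTACAGCTTTATCGCCCCTCGGTGGCCACAAGGTTCCCAGATGCGAAAGGGATCACTGGACTCCCAA
ATCGAACCCCTTGGATATTGCCGAACTAGCCTTAGCATTCACCGTGAGTACAACGTCCGGTCGGCCTTCTCTAGGTAATA
GAGGGGGTTAGTAAGATAGCCAATACGACCGATTGCTGGAGAGATTCAGTGCCATCTAGGACGTAGCGATTTAAACTGCG
GTCGTTCGTGATGCCGTTTATGTCTCCTAATCATGATCTCAAGCAGTAGATCGGCATAATCTTACAATGCAGGACTGGTG
TCAGCTGATCACTATTATGGTGCAGTAAGCGGTTATACTACACAGTAGACGAAACTACGCTCCTTCGAAGACAATCCATC
ACCTGAAGCTACTCGCGTAAGACTAGGTCCCGTAAAAACTTTGCGTCAATGCAAGGCTACCCCTACAAATTACCTGGATT
TGACACGATTAAGTAGGTGTGTCCCATGATATGGTCTGAGACGGGCCCAATATCTAAAATTTCCCACGGTAAATACCCCG
CACTAAACGAAGACGCTTAGGAATGCGCCGGTCGCCTAGTGTGGGGGGTCGGGCATGGCGGGAGGCTTCTGTACGAACCG
TCGTCACACGTTCCCCTCTAATTACGAACTCCTAAAAATTTCGTTGCAAGATTTTGGAGCGTAGAAAAGGAGTATCGGCG
CTTTCTGAACTCAGATAGCGTCTGTGTTCGGTTCGCAGGATCTATCTAGTTCGGCGGGGCGACGTTTTCGCCAGCAGCCG
CCCGTGCAAGTACTAGTACGTCAATTAAGAACCACTCGCCTATGCGGAATGACAGATTTACCTTTCGTGGCACACCCTAA
ACGTAGCATTTTAACGTACACCCGTAGGCAAGAAGACTGAACACCATTCTATGCGTGCTCTTCCGGCGTCGTACTCCATT
GCAAGTAAGCTTGGAAAGGAGACAAGAACGGAACCTAGATCGTGTGTGGCAGTGTCGCAACATAGTATCCCGATTCGGCT
CCGAGTTTGTCTCTTAGATAGCGTAACCCACTCCGATGCAGCAAATACACTGACTGGTCTGATATATGACCACAGAATGG
TTTGACCACTCGGTTTCGGATCAGGCCTTATAGCCTTTAGCGCCTTGGTCAGTCGACCACTTGCTCTTAACTAAGACGCC
AAGGGATCCGCAGGTCCTGAAACTGCTTTCGGTGGATAACGCTCAGCAGGCACTTAGGGATTCGAGTGACAGGCCCAGGC
GAAGTTCCCATCCTGTATCTGAACAGAAATCATTCCATGGTTTCTATTTAGGCTCGTCCGCAGATAATCGCTGCTAACCA
CGCAAACATAAAGAGTCAGAAGGGTCCCGGCGAGGATACACATGGTCTAAACGTTTGGGTTTTACTCTGCCGGGGGGTTG
GCAGCAAAGTATAGTCTGCTAATTCCCATTGTAATTGGCTTCAGCCAGACTCAGATGAGTCTGTTAGGTATATGTCGTAG
CAACTAATTTCGAATGGCAGTCATAAGGCGCCAGCATTGAGTTTATCGTGGGTTAAGAAAGTGCAGGATAATCTTGTTTT
CACGAGGTTGGCTCGGGTACCAGAGACCTTATGGAATGTTGAGGACCCTGAAACCGTCCCTAACGGTCCGCGAGGGGTCC
TGTTATAGGTTCTCTACTCCCGTAGGGGAACTGTGAACACGGCACGTATGGGACATTTCTGGCCTAAATGACCTGTATCG
GAGTCCCTTTGGTCATGAGATGGTAGCCACATCCTTGTCATCTTGGACGATCGCCAGTCTAGACCGGGCACTGCAAGTAT
CTATGTGGGGTAACTATGTAGACATGGCTTTCGCAAAGGTTAGATGCTTGACAAAGGTCAAGTTAGGTTGACATATAAGC
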