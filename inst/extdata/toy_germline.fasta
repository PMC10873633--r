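>IGHV1-2*01|IGH|V|285
TTCAGAACCTGGATCAATCTCGAAACATGCACCAGACTCTTGAGGTCATACTCAATACCCGGTATCAGTGATTTGAGAAG
GAGTGGGAGTCAAGCTCGTCTGCTAAATAACGCGATCCAAACCAGGGCAGTTCTAATAGTGGCTCTACCTATAGACCTTG
CTTGTAGCACCACAGCCACAGGTACAAAACCGTATAGGCGGAGTAGGGGCTACCCTTCGGTCATAATATCTACTCTTCAT
CCCCGTGCTCCGCGCTCTGCTGGGTCTGCACTCACCAATACCTCTTGTGCC
>IGHV1-69*01|IGH|V|285
CCCCTTAGAATTAAGGCAAAACCCTCTTGGCATTTTAATAGGCAAAATCTCATGCTAGGTATCTTGGAGTCGCGACTGAA
GAAATTATACTACCACACTCTTAAGCATATCCGCGAAAGGCTCAGTAAGGCCCTTCGAAACGTGGTGGGCAGGCGTCTAC
CCTTCAACCTTAGTTTACAACATCGCCTATTGCACTCCACCATAACAATTGCCGCGCTCACTCATTTTGAGAAATCGGTC
ATGGGGTCCGTAGATTTTACGCGCTCAGCACGAATCTTATATACTTGTCTG
>IGHV3-7*01|IGH|V|285
TACACAGTAATCGCGACGGAAGACAAGCTGATGGTACTTCAAAGCTTTGTCTACTCACTTTGGTGGGAGTGGCGGCGTCG
TCCTATTAAAGAATTCATTCGCGGGGATCCACGCTGGTATCTCTATAGTACCATTATATCTAAAAAACGAAGCAGAATCC
AGCCACCTTACGTCATTGTTATCATGCTGACGCACGCGTGGCGGAAATTTTCTGCGCCCCTAAATTCGGAAAGTATCCGA
CTGACTACATTCTTTAACTCGACATCACCCTCTTGCATTATCTATTGTCCA
>IGHV3-23*01|IGH|V|285
GCCGTGTGTCAGATCCGATCGAGTTCTACAGGGTGGATCACATACGTAAGTACTCAGATGCCTAGCCACGGACCGGTATT
CCCGCCCGTTAGAAAGGAGCGACCTTCGGACGGCGAAGGGCTACGACACAATGGGTGGCTTGAACGGCACTTGGGTGTAA
CGCAAGTACTTGGCCGCGACCACAAATGCCACCTAGTAGCTGGGGGGACACGGGGTAATTTCCGCGACGGAGGCCGCGAA
TTTGCGACACCAGCTGTCACCTCAACCATATGTCCTGGGGGCCGGTGTTCG
>IGHV4-34*01|IGH|V|285
GCCCCGGTGCAAGTGACATGTACTGGCTTGAAGGACGATATCGTGGTCGGGGGCAATAATCGGCAGGCCTGTCAGTGTAA
TCCTCGGGTTGTTGGACAACGGCGGGATGCCAAGTTCCAAAGCAGCCCGATAACTCACTCGTGCGAGATGCTACCTATCG
TGGCGCTCACTTCCGTCACGTGTGTGAGGCGATACAGGTTGCCTCATCTCCGATCTACTCAAAGTCGCCGACATACACAC
TCCTGTCACTGTACTGCCACTCGGGGTAATTCCCTAAAAGTGATTTGTAGG
>IGHD2-2*01|IGH|D|
AAACCCTTCGGTTTC
>IGHD3-10*01|IGH|D|
CCACTTTGTATCACAGTG
>IGHD6-19*01|IGH|D|
AATTGTTGCATGGGGAAAGCC
>IGHJ3*01|IGH|J|12
GGGAGTACACCCTGGAGCCTCCACCCGTGGCGTTATCTGACACTTGAG
>IGHJ4*02|IGH|J|12
TCGGCAGTAAGGTGGGGGTTACGAGCAGTATCAAATGAGAAAGCGTGC
>IGHJ6*02|IGH|J|12
AGCAGCACTATATGGCCTAGAGCGCAAGCTATTCAGCCCAAAACCCCC
>IGKV1-5*01|IGK|V|285
CGTAGCGAGCACAGACCTGCTCTAATTGGCCAGCTTCCTTTCCCTTACCTACCCAAAAGAGCGCCCCCACCGATTAGAAT
CGGGGAAACAGGTGCGAATGGGATATGCTGCATTAAGATCTCGACTACGCCGCCCAATCAGTATGGTCAACTGCGCCGCA
TCGAACGCGTGCCCTACGACGAGAGCATTTCCTGGTATGTGCTCAATTCCTGCAGTTATTATTGGGAGCTGTTGCCCTCT
CGGGCTAGCGAAGAGATGTCTGGGCCAAAGATTGCGCTAATCGGATGTCTA
>IGKV1-39*01|IGK|V|285
CATAATTATCTACGATCAGTCAGGTACAACCTTGGTTTTCATTACAGGGACGTCCTACATCGAATCGCTTGTTTTGCCGC
CGTAAGATATGAGCGACTCATATCGTCATATGCCGGTATTGGGAACCCTAATCGGTCGATATCTCACGTGGCAGAACCCT
ACTGTGCAACGTCAAACAAAAAAGGGGAGCCTTTCTCGCCGAGGTCTTTAGTATCGACTACCGTTACTTTCTCGCGATAC
CCTCTGTGGTTGTCTGTCCATATAGCGTGCAAGTTCAAAAGCACGTGTCAA
>IGKV2-28*01|IGK|V|285
AGGACACAGACCAGGTCTGTTAATCACTGTGTCGTAGTTCGGTGTATCGGTGTACCCATACTTAATCTCAACTTGGTGTT
AATCCACCGATCTGGAGCTGGTCTTTCAAACGGAGGCTTTGAAGTAGAAACTCCGCCAACTGTTACGATGAGGCACGGAG
AGGCATCGAAACCGAGAGATGAGGGCGAAGAAAACAACGCGAAGCGATCGTGGTGGAAGCCCCGGCACAGGGCGTCTATA
CAGAAGACAAGTGAGAGATTTCTCTACGGAAACTCGGTACACCGATGTGTA
>IGKV3-20*01|IGK|V|285
TCTGACCGAGACCTTTTGGGGGGAGACAATCCTGCCTATCCTTCGCCAATGTGCTTTCCGACTACAGCCCAAACAGAACC
CTTTGCCGCACTCCGGGCAGCCATCCAGTTCAAGTCAGGTCTATCTCGTGTTCCCTATAGCCCATCTAAGGCGTTAATTC
GAGTAAGGTCAATTGTGAGCATTGATGTTATCCTAACTGTGGGTGCGTTCGATCAATGGCATCAGCGGGTTGGCCCGCAA
GCTCAAATGCTTCTTGCTAGCGCATTACGCCCTCGACATGGCCGGTGTGGA
>IGKV4-1*01|IGK|V|285
ATTTCGATAATGGTGAAGTTACCGATCAGTGAAAGACTGAAGCTTTCAGTGATGGAGCTCGATGAGTTTCTTCGGGGTGA
CTTTTTTACTGTGAGCTGTGCGGTAAACACATTTGAAGTCCTGTATATTTTCGTTAAAACTTACTACATAGGCGTGCCCG
GCTCCGGCGCAGAAACTCTCCCGACACTACCCCTACGATACATTACGGACCATGCGTGCAGAAGTCAGGTCGTTGGGTAT
GTACATAAACTCGACAAGTCCGAGAAGCGGTGCGATGTGCAACTATGTTCG
>IGKJ1*01|IGK|J|9
GTCGTACGTTTCGAATCCATTCTACAGCATGATGACAAA
>IGKJ2*01|IGK|J|9
GGGTTCGTTTTCGGAGGCGGTACCAAATCGGCCTCAGTC
>IGKJ4*01|IGK|J|9
CATTAGGATTTCACGAGAAACCAATCCGCTAGAAGGGGC
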