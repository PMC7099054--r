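>IGHV1-2*01
CAGACCAGATTATCTTATACGTCGTTCTCGACCAGTCTAGTGCTCCTGTTCAGCTGTCTATTGTTCTGCTTGGACCTGCTCGTCAAAACG.........ATGCGGATCTCCTCCAGTGCGTGGCGAAAGCAGTCATATAAATGTCCAATTGAGGCTATGACTAAGCGATTGGCCCGCCCT...GTGGAGAGCACATGCGGTGACTGTAAGCGATCATGCTGTCACTGGGATTGGGCGTGTCGCTTTCATCTCGCTCCTGAACTAGTGGACCCGATCGGAGTTGCTCGCATCTCAAGCTGTTCGAAGGAATGC
>IGHV1-18*01
CAGACCAGATTTTCTTATACGAGTTTTTCGTTGAGTCTAGTGGCGCTGTTCAGCTGTCTATTGTTCTGCTTGGACGGTCTCGTCAATTAT.........ATGACGCGATCCTCCAGTTGGTGGCGAAAGCAGTCATATTCGTGTCCATATGAGGCTCCTACTAAGCGATTGTGCCGCCCT...GTTGAGAGCACATGGGGTGACTGTAAGCGAGTCCCCTGTCACTGGTTGTGGGCGGATAAGTTTCATTCCAGAGCCGAACTACACGACCCGATCGGAGTTGCTCGCTTCTCACAGTGTTCGAAGGAATGC
>IGHV1-46*01
CAGACCAGATTTTCTTATACGAGTTTCTCGACCAGTCTCGTGCTCCTGTTCATTGTTCTATTGTTCTGCTTGGACGGTCTCGCCTGGACG.........ATGACGATCTCCTCCAGTTGGTGGATAAAGTATTCACCGAGTTGTCCAAGCGAGGCTATGACTAAGCGATTGGCCCGCTTG...GTGGTAAGCACAACCGGTGACCCTAAGCGAGTCTGCTGTCACTGGTTGTGGGCGTGTAAGTTTCATCTCAGAGCCGAACTACACGACCCGCGGGGATGCGCTCGCATCTCAGGCTGTTCGAAGGAATGC
>IGHV1-69*01
CAGACCAGATATTCTTATACGAGTTTCTCGACCAGTCTAGTGCTCCTGGGGTGTTGTCTACCGTTCTGCTTGGACGGTCTCGTCTGGACG.........GGCCAGATCGCATCCAGTTGGTGGCGAAAGCCACAGTATAGTGGTCCAATTGAGGCTATGACTAAGCGATTGGCCCGCCCT...GTGGAACCTACATGGTGGGACTGTAAGCGAGTCGCTTGTCACTGGCGGTGGGCGTGTAAGTTTCATCTCAGAGCCGAACTACACGACCCGATCGGAGTTGCTCGCATCTCACAGTGTTCGAAGGAATGC
>IGHV1-69*02
CAGACCAGATATTCTTATACGAGTTTCTCGACCAGTCTAGTGCTCCTGGGGTGTTGTCTACCGTGCTGCTTGGACGGTCCCGTCTGGACG.........GTCCAGATCGCATCCAGTTGGTGGCGAAAGCCACAGTATAGTGGTCCAATTGAGGCTATGACTAAGCGATTGGCCCGCCCT...GTGGAACCTACATGGAGGGACTGTAAGCGAGTCGCTTGTCACTGGCGGTGGGCGTGTAAGTTTCATCTCAGAGCCGAACTACACGACCCGATCGGAGTTGCTCGCATCTCACAGTGTTCGAAGGAATGC
>IGHV2-5*01
CAGGAATCATACTGGGATTGGCCACGTAGCTTTGCCTTGCATCTATTCCAGGCGGAGGGACCAGGCTGCGCGAGTTTACCAGATTTGAATTTT......GTGATCGACATGTGCTACTGGTGGTTTCAAACGGTTATCCCGTTCTATGCTTCCGTGTTTGCGCGATTACCATTCCTG.........CAAACATGCCTTTGCGAGCTATCACCGATCCTCCCGCTCAAGTTTGACTTATCTTACAACATAATTGTTACTTGCCTGGTGACCTGTCGGCCCTGCCCCTGTTTCCTTTATCAATCCCTGAGCTGC
>IGHV2-70*01
CAGGAACTATACTGGGATTGGCCACGCAGCTTTCCATTGTACCTATTCATGGCGGAGGGACCAGGCTGCGCTAGTTTACCAGATTTGAATCTT......CTGATCGACATGTGCGGCTGGTGGTTTGTCAATGTTATCCCGAACTATGCTCAAGTGTTTTTGCGATTACCATTCCTG.........CAAACATGCCTTGGCGAGCTATCACCGGCCGGTTCTCTCCTATTTGACTTATCTTACCCAACCATTTTACCGTGCCTGGTTACCGTGCGGCCCTGCCCCATGTTCCTTTCCCAAAATTATCTCTGC
>IGHV3-7*01
CAGTTCGACATGATCCGTAACGGCAAGCTTGGGGATATGCTCCGCGAGATTACCAAGAAGTCACTGTGCATTCTAACAAACAGTATTGGA.........GCCTGGTCCCTACCCCAATGTTGGATATCCCGTGAAGCACCTAAGGTTCAGACGATGCCAATACCGGGTGCTCCATCC.........CTACCGAATTATTCAGCTCTCAGCACCGATGGTGCTTGCAAGCACGAATCTGGAAGGTTGTCACCCAATGGTCTCCACGCTGTCAGCAAGTCCAACACGTACAAACTCACTCAGCTGCGTAAATGC
>IGHV3-23*01
CAGATTTATATGATCCGTAACGGCAAGCTTGGGGATATGCCTCGCGAGATTACCAAGAAGTCACTTTGCCGCCTAACAGCAAGTATTGGA.........GCCACTTCCCTACCCGTCTGTTGGATATCCCGTGAAGCAAATCTGAAGCTAACGATGCCAATACCGGGTGCTCGACGG.........CCGCCGAATCACTCAGCTCTCAGCACCCTGGGTGCTTCGTGCCACGAAAGTTATAGGTTGCGCCCCAATGGTCTCAAGGCTGTCAGCAAGTCCAACACGTACAAAAGCACTCAGCTGCGTGCGTGC
>IGHV3-23*02
CAGATTTATATGATCCGTAACGGCAAGCTTGGGGATATGCCTCGCGAGATTACCAAGAAGTCACTTTGCCGCCTAACAGCAAGTATTGGA.........GCCACTTCCCTACACGTCTGTTGGATATCCCGTGAAGCAAATCTGAAGATAACGATGCCAATACCGGGTGCTCGACGA.........CCGCCGAATCACTCAGCTCTCAGCACCCTGGGTGATTCGTGCCACGAAAGTTATAGGTTGCGCCCCAATGGTCTCAAGGCTGTCAGCAAGTCCAACACGTACAAAAGCACTCAGCTGCGTGCGTGC
>IGHV3-30*01
CAGTTCTCTATGATCCGTAACGGCAAGACCGGGGATGATCTCCGCGGCATTACCAAGAAGTCACTGTGCATCCTAACATGTAGTATTGGA.........TCCACTGTGATGCGACAATGTTGGATATCCCGTGGGGCACCTAAGAAGTCTACGATGCCAATACCGGGTGCTCGATCC.........CGACCGAATGTGTCAGCTCTCTTCACCCTGGGTGCTTGGAAGCACGAAAGTTATAGGTTGGATCCCAATGGTCTCAAGGCTGTCAGCAAGTCCAACACGTACAAAAGCACTCAGCTGCGTGCGTGC
>IGHV3-48*01
CAGTTCTCTCGGATCGAAAACGGCAAGCTTGGGGATATGCTCCGCCTAATTACCAAGATTTCACTGTGCCGCCTAACAGGTAGTATTGGA.........GCCACTTCCCTACCCCAATGTTGGATATCCTGTGAAGCACCTAAGAAGCAGACGGCACCAATACCGGTAGCTCGATCC.........CCGCCGAATGTGCAAGGGCTCAGCAGCCTGGGTTCTTCGAAGCGTGAAAGTCGCAGGTTGGATCCCAATGGTCTCAAGAGTGTCAGCAAGTCCAACACGTACAAAAGCACTCAGCTGCGTGCGTGC
>IGHV4-4*01
CAGTGCTGGGGTCGTACGTGTAAGGGATATACCGCGAATGTGCACACTTTTCAGTACGGAGCGCCTTGCGGTCTGAGCCGAAGCTGTACG.........GCCGGCGGATTACATAGCCACTGGAAGCGATGTTTCATGACACGACTCCAATACCGAACAGAATCGCGGTATTACAGTGAAAACCAGCTGCGATTTCCATTAGGCGATTGTAGTAAA...ACCGACACACCGCGAACACTAGTCAAGATCCATTTGTGGGACCGAGACATATGCAGTCGGCGAGGGCGCCGCTGGGCCCATAAGAGCGGATGC
>IGHV4-34*01
CAGTGCTGGGATCGTACGTGTAAGGGATATACAGCGAATAAAACTACTCTGAGATACGGACGTATATGCGCTGTTTATCGAGTCTGTACG.........CTAGGCAATTTACATAGCTCTTGGGTACGATTGTTCATGACACGACTCCAATACCGAACAGAATCGCGGAATCATAGTAGCAACCAGCTGCCGACTCCATTAGGCGATCTTACGAAA...ACCGTTATTCCGCGAACACAAGTCAAGATCCATTTGTGGTGGCGAGACGAGCTTAGTCGGCGAGGGATGCGCCTGGCCCATAAGAGCGGATGC
>IGHV4-34*02
CAGTGCTGGGATCGTACGTGTAAGGGATATACAGCGAATAAAACTACTCTGAGATACGGACGTATATGCGCTGTTTATCGAGTCTGTACG.........CAAGGCGATTTACATAGCTCTTGGGTACGATTGTTCATGACACGACTCCAATACCGAACAGAATCGCGGAATCATAGTAGCAACCAGCTGCCGACTCCATTAGGCGATCTAACGAAA...ACCGTTATTCCGCGAACACAAGTCAAGATCCATTTGTGGTGGCGAGACGAGCTTAGTCGGCAAGGGATGCGCCTGGCCCATAAGAGCGGATGC
>IGHV4-39*01
CAGTGCTGGATTCGTACGTGTAAGGGATATACAGCGAATGTGCACACTTTTAGATACGGACGTCCTTGCGGTCTGAGCCGAATCGTTACG.........CTAGGCGGATTACATAGCTCTTGGAGTCGATTGTTCCTGACACGACTCCAATACCGATCCGAAGACCGGTATTACAGTATTAACCAGCTGCCGTTTCCACGCGGCGATTGTAGTAAA...ACCGTTATTCCGCGAACAATTCTCAAGATCCATTTGCAATGGCGAGACCACCTTAGTCGGCGAGGGCGCGCTCTGGCCGGTAAGGCGGGATGC
>IGHV4-59*01
CAGTGCTGGGGTCAGACGTGTAAGGGATATACAGCGAATGTGAAAAGCTTTAGATACGGACGTCCTTGCGGTCTGAGCCGAAGCCAGACG.........CTAGGCGGAGATCATAGCTCTTGGAAGCGACTTGGGATGACACGACTCCAATACCGAAGCGAATCGCGGTATTACAGTATTAACCAGCTGCCGTTTCCATTAGGCGATTGTTCTAAA...GATGTTATTCCGCGAACACTAGTCAAGATCCATTTGTGGGTGCGAGACGAGCTTGTACTCCGAGGGAGGCGCCTGGCCCATACGAGCGGATGC
>IGHV5-51*01
CAGAGAGCGCAGAGCGTTCGTAACCGCCCAGGCCACGTTTGGAGCGAACCAACTGTACCAGCGGTCTGCAGATTGTTCTACACCGCGACGCAA......GCGGCTGTAAAATATCCGGTTTGGGCGGCCATAATAGTCCAATCTATCCATCTTGAACTCCTTGATGGCATGGAACCGCAA......ATATACTGTCGGGTTTACTTTCTAGCTTGGGGCCCTCGTTTCGCCAAAAGATCTCCCTCTATATCCGGATCGAATATGGAGAGAGGGGATACTGCTAGCCATAGAGCCCTCCCTGAAGCTTTATGC
>IGHV5-51*02
CAGAGAGCGCAGAGCGTTCGTAACCGCCCAGGCCACGTTTGGAGCGAACCAACTGTACCAGCGGTCTGCAGATTGTTCTACACCGCGACGCAA......GCCGCTGTAAAATATCTGGTTTGGGCGGCCATAATAGTCCAATCTATCCATCTTGAACTCCTTGATGGCATGGAACCGCAA......ATATACTGTCGGGTTTACTTTCTAGCTTGGGGCCCTCCTTTCGCCAAAAGATCTCCCTCTATATCCGGATCGAATATGGAGAGAGGGGATACTGCTAGCCATAGAGCCCTCCGTGAAGCTTTATGC
>IGHV6-1*01
CAGCTCGGCCGCCGTGGTGGACGGCAACTCCGCTGCAAAGTAGATGACGGCATGCCAGGCTCTAACTGCCATGAGAACTCTTTTTGTGCAGCTCTGCAATGCGAGACCCACAATGTGGTGTGGAATCCATTGGCTTTCCTTCGAGAGCCGTCACAAATCGCTCCCATCGTTTCGAAATCCAACTCTGGATTACGCTTGCAAAAGATTCTTGCTAGA...ACTTGTCATAGCCTCGATATCGAGCTAGGTGATTACCGACAATGCGAGACATCTGGGCAGGGTGACGTAGCGTTCAGTCTATCATGCTCCTGC
>IGHV7-4-1*01
CAGTCAAAGTGGTCCAGGCCATTAGACAGTCCCCGTCGCGTTAACAGGCGGCATTCTGAGATGACGTGCATGTTCTGCTTACCGCAACGC......ACATACACGGGCCCTACGCACGTATGGAAAAATTATACTTACCTCGTACGAATGTGCTGCCACTCAAGAATTATGCATGGGGAC...GTTATTATCACTCTCGACGAGACCTTACTTGGAAACACTCACATGGAATTCATTACTAACACCAGACTGGTTGCCCGATGCCTTCCAACCCTAAATCTGATTACTCGTCGCGCGGCCCAATGCAATTGC
>IGHV7-81*01
CAGTCACCTTGGTCCAGGTATTTAGACTACTTTCGTCGCGTTAACAGGCGGCCAGGAGAGATGACGTGCATGTTCTGCAGCCCGCAACGC......ACATACACGGGATCATGCCACGTATGGCTTAATTATACTTACGGGGTACGAATGTGCTGCCACTCATGCAGAATGCATCCGGAC...GTTATTATCACTGCTCATGAGACCAGCCTTTCTAACACTCACATGGGCTTCATTATAAACGACAGAGGCGTTGCCCGATGCCTTCCAGGACTAAATCTGATTACTTTACGCGCGGCCTGTTGCAATTGC
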