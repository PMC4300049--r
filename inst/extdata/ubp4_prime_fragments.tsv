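# Oligo set for the 276-nt Ubp4' gene analogue (assembly fragments + PCR primers).
# Names use ASCII "p" for the prime mark. Odd-numbered rows are main chains
# (coding strand, 5'-phosphorylated), even-numbered rows are helper chains.
# Primers are for final PCR amplification only and never enter assembly planning.
name	role	sequence
Ubp4p1	main	ATGTGCTACATGAATTGTATAATACAGTGTATCCTAGGAA
Ubp4p2	helper	AATCTGGGTCAGCTCATGCGTTCCTAGGATACACTGTATT
Ubp4p3	main	CGCATGAGCTGACCCAGATTTTTCTCGATGACTCCTACGCTA
Ubp4p4	helper	TAGAGTTAATATTGATGTGCTTAGCGTAGGAGTCATCGAGA
Ubp4p5	main	AGCACATCAATATTAACTCTAAACTAGGCTCTAAGGGCATCTTGG
Ubp4p6	helper	GCACGAGTCGAGCGAAATACTTTGCCAAGATGCCCTTAGAGCCT
Ubp4p7	main	CAAAGTATTTCGCTCGACTCGTGCACATGATGTATAAAGAGCAAGTA
Ubp4p8	helper	GGGGAAATGGATATTTTCTTAGAACCGTCTACTTGCTCTTTATACATCAT
Ubp4p9	main	GACGGTTCTAAGAAAATATCCATTTCCCCAATAAAATTTAAATTAGCATGTGGATCCGT
Ubp4p10	helper	GCGGTTTTGAACAACGAGTTTACGGATCCACATGCTAATTTAA
Ubp4p11	main	AAACTCGTTGTTCAAAACCGCCTCACAACAGGATTGTCAGTAA
Ubp4pFor	primer	GGGGGAATTCGATATGTGCTACATGAATTGTATAATAC
Ubp4pRev	primer	GGGGGGATCCTTACTGACAATCCTGTTGTGAG
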