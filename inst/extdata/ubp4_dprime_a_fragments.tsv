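# Oligo set for the 540-nt Ubp4''a gene analogue (first half of the 1083-nt
# Ubp4'' design). Names use ASCII "pp" for the double-prime mark. Odd-numbered
# rows are main chains (coding strand, 5'-phosphorylated), even-numbered rows
# are helper chains; primers are for PCR only.
name	role	sequence
Ubp4ppa1	main	TTCGCGGTGGGCCTCGAGAATCTAGGAAATTCCTGCTATATGAACTGCATTATCC
Ubp4ppa2	helper	CAGCTCATGCGTCCCTAAAATACACTGGATAATGCAGTTCATATAGCAGGAATTTCCTAG
Ubp4ppa3	main	AGTGTATTTTAGGGACGCATGAGCTGACGCAGATCTTCCTTGACGATTCGTATGCGAA
Ubp4ppa4	helper	CCCTAGTTTAGAATTGATATTGATGTGCTTCGCATACGAATCGTCAAGGAAGA
Ubp4ppa5	main	GCACATCAATATCAATTCTAAACTAGGGTCGAAAGGTATTTTAGCTAAATATTTCGCTCGTCTTGTAC
Ubp4ppa6	helper	TTGGAGCCATCTACCTGTTCCTTATACATCATATGTACAAGACGAGCGAAATATTTAGCT
Ubp4ppa7	main	ATATGATGTATAAGGAACAGGTAGATGGCTCCAAAAAAATTTCGATTAGCCCAATCAAATTTAAGCT
Ubp4ppa8	helper	AACAGTGAGTTGACGGAACCACAGGCGAGCTTAAATTTGATTGGGCTAATCG
Ubp4ppa9	main	CGCCTGTGGTTCCGTCAACTCACTGTTTAAAACAGCTTCACAGCAAGATTGTCAGGAATTTTGCC
Ubp4ppa10	helper	GATCTTCATGCAAACCGTCAAGCAAGAATTGGCAAAATTCCTGACAATCTTGCTGTGA
Ubp4ppa11	main	AATTCTTGCTTGACGGTTTGCATGAAGATCTGAACCAGTGCGGTTCTAACCCC
Ubp4ppa12	helper	CCTCTTGGCTCAGTTCTTTCAACGGGGGGTTAGAACCGCACTGGTTCA
Ubp4ppa13	main	CCGTTGAAAGAACTGAGCCAAGAGGCAGAAGCGAGGCGGGAAAAGCTGAGCCTC
Ubp4ppa14	helper	GTTCCCATTCAATACTACTGGCTATGCGGAGGCTCAGCTTTTCCCGCCTCGC
Ubp4ppa15	main	CGCATAGCCAGTAGTATTGAATGGGAACGCTTTCTGACCACGGATTTTAGCGTCATTGTG
Ubp4ppa16	helper	AGCGAGAGGCATATTGCCCTTGAAAGAGGTCCACAATGACGCTAAAATCCGTGG
Ubp4ppa17	main	GACCTCTTTCAAGGGCAATATGCCTCTCGCTTAAAATGCAAAGTATGCAGCCACACTTCA
Ubp4ppaFor	primer	GGGGGAATTCGATATGTTCGCGGTGGGCCTCGAGAATC
Ubp4ppaRev	primer	GGGGGGATCCTTATGAAGTGTGGCTGCATACTTTGCATTTTAAG
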