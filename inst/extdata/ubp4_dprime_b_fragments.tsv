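# Oligo set for the 543-nt Ubp4''b gene analogue (second half of the 1083-nt
# Ubp4'' design). Odd-numbered rows are main chains (coding strand,
# 5'-phosphorylated), even-numbered rows are helper chains; primers PCR only.
name	role	sequence
Ubp4ppb1	main	ACCACATATCAGCCCTTTACGGTACTGTCTATCCCTATACCCAAAAAGAATA
Ubp4ppb2	helper	AGCAATCCTCGATAGTAATGTTATTGCGACTATTCTTTTTGGGTATAGGGATAGACAGT
Ubp4ppb3	main	GTCGCAATAACATTACTATCGAGGATTGCTTCCGCGAATTCACCAAATGCGAAAATCTCGAGGTAG
Ubp4ppb4	helper	TTCACAGTGCGGACAGAGCCATTGCTCATCTACCTCGAGATTTTCGCATTTGGT
Ubp4ppb5	main	ATGAGCAATGGCTCTGTCCGCACTGTGAAAAACGTCAACCGTCAACTAAACAGCTGACCATTACC
Ubp4ppb6	helper	TTTTAGATGGACAATGAGGTTCCGCGGCAAGCGGGTAATGGTCAGCTGTTTAGTTGACGGT
Ubp4ppb7	main	CGCTTGCCGCGGAACCTCATTGTCCATCTAAAACGTTTTGATAACCTGCTTAACAAAAACA
Ubp4ppb8	helper	AGCAGAAATGGATAAATCACGAAGTCATTGTTTTTGTTAAGCAGGTTATCA
Ubp4ppb9	main	ATGACTTCGTGATTTATCCATTTCTGCTGGATTTAACGCCTTTTTGGGCAAACGACTT
Ubp4ppb10	helper	TTCACCCCCGGCGGGAACACGCCATCAAAGTCGTTTGCCCAAAAAGGCGTTA
Ubp4ppb11	main	TGATGGCGTGTTCCCGCCGGGGGTGAACGACGATGAATTACCAATCCGAGGTCAGATCCCGCC
Ubp4ppb12	helper	CACGCGACACCATACAATTCATATTTAAATGGCGGGATCTGACCTCGGATTGGTAATT
Ubp4ppb13	main	ATTTAAATATGAATTGTATGGTGTCGCGTGCCATTTCGGGACACTGTATGGCGGCCAC
Ubp4ppb14	helper	TTAAACCTTTTTTCACATAAGCCGTATAGTGGCCGCCATACAGTGTCCC
Ubp4ppb15	main	TATACGGCTTATGTGAAAAAAGGTTTAAAAAAGGGATGGCTTTATTTTGATGA
Ubp4ppb16	helper	GCGTCGGCTTTGTTTTTAACCGGCTTATACTTGGTATCATCAAAATAAAGCCATCC
Ubp4ppb17	main	TACCAAGTATAAGCCGGTTAAAAACAAAGCCGACGCAATTAATAGCAATGCATATGTTCTGTTCTAT
Ubp4ppbFor	primer	GGGGGGATCCACCACATATCAGCCCTTTACGGTAC
Ubp4ppbRev	primer	GGGGTCTAGATTAATGGTGATGGTGATGGTGATAGAACAGAACATATGCATTGCTATTAATTGCG
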