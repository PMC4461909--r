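intron_id	exon_end6	donor16	acceptor16	next_exon10
intron_1	AAAAAG	gtgggcttctttatct	ctttttcccgtttcag	ATCCTTGCTT
intron_2	AAGGAG	gtaagttcgcaacctc	cctcctctctttgcag	CCAATCATGC
intron_3a	TACCAG	gtacgtgtcttccgct	cattatatcatttcag	TCCCTCCAAA
intron_3b	GATCAG	gtgagtgctagaagtc	tattatcccctttcag	ACGATGAACT
intron_4	ACGAAG	gtatggccgagtgttc	ttccgttcctacgcag	GTCAAGCCGT
intron_4ex	TAAAAT	gtacgcaagagattcg	ttccgttcctacgcag	GTCAAGCCGT
intron_5	TGACAG	gtacttgaactaatta	ccaaccaacaaaacag	CTCAGGCTGT
intron_6	GCGAAG	gtgagttgagcattgt	cttatcatcattacag	ATGCCGCTAG
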