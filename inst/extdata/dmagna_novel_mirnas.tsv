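mirna	mature_seq	length_nt
miR-nov-1-5p	GGUGAGCCGGCGUUUCGGGAUUU	23
miR-nov-1-3p	GUUUCGAACGUCGAGCCAACC	21
miR-nov-3-5p	UCUUGGUUGCUCGGUCUUUAGG	22
miR-nov-3-3p	UAAAGCUCGGCUAGCAGGAUCC	22
miR-nov-4-5p	CCAGUUUAACAUAGCCCACAGA	22
miR-nov-4-3p	UCUGGGUUAUGAUUAAGACUGGG	23
miR-nov-10-5p	UGAAGCAGAGGACUGCUUUGA	21
miR-nov-10-3p	UGAGAGCAGUUCUCUGCUUCAUU	23
miR-nov-12-5p	GGGGGGAACUUUACUCAGUUUGAU	24
miR-nov-12-3p	UCACUGGGUACGUUCGCCCUUG	22
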