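mirna	variant_id	mature_seq	variant_seq	expected_class
miR-1175-5p	v1	AAGUGGAGCAGUGGAUC	AAGUGGAGCAGUGGAUCU	ISO_3P_TEMPLATE
miR-12-5p	v1	UGAGUAUUACAUCAGGUACUGGU	UGAGUAUUACAUCAGGUACUGG	ISO_3P_TEMPLATE
miR-210-5p	v1	AGCUGCUGAACACUGCCCAAGAU	AGCUGCUGAACACUGCCCAAGA	ISO_3P_TEMPLATE
miR-279b-3p	v1	UGACUAGAACCCACACUCGUCCGG	UGACUAGAACCCACACUCGUCCG	ISO_3P_TEMPLATE
miR-285-3p	v1	UAGCACCAUUGGAAUUCAGUUU	UAGCACCAUUGGAAUUCAGUUUA	ISO_3P_TEMPLATE
miR-2944-3p	v1	UAUCACAGUCGUAGUUACUAGA	UAUCACAGUCGUAGUUACUAG	ISO_3P_TEMPLATE
miR-31-5p	v1	AGGCAAGAUGUCGGCAUAGCUGA	AGGCAAGAUGUCGGCAUAGCUG	ISO_3P_TEMPLATE
miR-71-5p	v1	UGAAAGACAUGGGUAGUGAGAUGU	UGAAAGACAUGGGUAGUGAGAUG	ISO_3P_TEMPLATE
miR-71-5p	v2	UGAAAGACAUGGGUAGUGAGAUGU	UGAAAGACAUGGGUAGUGAGAU	ISO_3P_TEMPLATE
miR-71-5p	v3	UGAAAGACAUGGGUAGUGAGAUGU	UGAAAGACAUGGGUAGUGAGA	ISO_3P_TEMPLATE
miR-9b-5p	v1	UCUUUGGUGGUCUAGCUGUAUGA	UCUUUGGUGGUCUAGCUGUAUG	ISO_3P_TEMPLATE
miR-9b-5p	v2	UCUUUGGUGGUCUAGCUGUAUGA	UCUUUGGUGGUCUAGCUGUAU	ISO_3P_TEMPLATE
miR-9b-3p	v1	UAAAGCUAGAUCAGCAAGGCAA	UAAAGCUAGAUCAGCAAGGCA	ISO_3P_TEMPLATE
miR-92b-3p	v1	AAUUGCACUCGUCCCGGCCUGC	AAUUGCACUCGUCCCGGCCUG	ISO_3P_TEMPLATE
miR-998-3p	v1	AUAGCACCACGGGAUUCAGCCGC	AUAGCACCACGGGAUUCAGCCG	ISO_3P_TEMPLATE
miR-210-3p	v1	CUUGUGCGUGUGACAGCGGCUAU	UUGUGCGUGUGACAGCGGCUAU	ISO_5P_TEMPLATE
miR-305-3p	v1	CGGCACCUGCUGGAGUGCAAUUG	CACCUGCUGGAGUGCAAUUG	ISO_5P_TEMPLATE
miR-9a-3p	v1	AUAAAGCUAGGUUACCAAAGUUA	UAAAGCUAGGUUACCAAAGUUA	ISO_5P_TEMPLATE
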