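node	sub_guild	role	phylum_group	layout_ambiguous
Corynebacterium_767	ASG	civilian	Actinobacteria	FALSE
Corynebacterium_1	ASG	civilian	Actinobacteria	FALSE
Corynebacterium_413	ASG	civilian	Actinobacteria	FALSE
Corynebacterium_291	ASG	civilian	Actinobacteria	FALSE
Actinomyces_167	ASG	civilian	Actinobacteria	FALSE
Capnocytophaga_384	ASG	civilian	Bacteroidetes	TRUE
Capnocytophaga_252	ASG	civilian	Bacteroidetes	TRUE
Corynebacterium_633	ASG	guard	Actinobacteria	FALSE
Corynebacterium_53	ASG	guard	Actinobacteria	FALSE
Corynebacterium_414	ASG	guard	Actinobacteria	FALSE
Corynebacterium_256	ASG	guard	Actinobacteria	FALSE
Corynebacterium_28	ASG	guard	Actinobacteria	FALSE
Corynebacterium_169	ASG	guard	Actinobacteria	FALSE
Corynebacterium_304	ASG	guard	Actinobacteria	FALSE
Actinomyces_500	ASG	guard	Actinobacteria	FALSE
Actinomyces_436	ASG	guard	Actinobacteria	FALSE
Bacteria_655	ASG	guard	Others	FALSE
Fusobacterium_608	ASG	guard	Others	FALSE
Leptotrichia_615	ASG	guard	Others	FALSE
Neisseriaceae_683	ASG	guard	Others	FALSE
valvarum_597	ASG	guard	Others	FALSE
Rothia_93	FBSG	civilian	Actinobacteria	FALSE
Rothia_492	FBSG	civilian	Actinobacteria	FALSE
Rothia_299	FBSG	civilian	Actinobacteria	FALSE
Actinomyces_426	FBSG	civilian	Actinobacteria	FALSE
Actinomyces_204	FBSG	civilian	Actinobacteria	FALSE
Streptococcus_250	FBSG	civilian	Firmicutes	FALSE
Streptococcus_521	FBSG	civilian	Firmicutes	FALSE
Veillonellaceae_681	FBSG	civilian	Firmicutes	FALSE
Veillonellaceae_70	FBSG	civilian	Firmicutes	FALSE
Veillonella_87	FBSG	civilian	Firmicutes	FALSE
Mogibacterium_78	FBSG	civilian	Firmicutes	FALSE
Thermophilus_6	FBSG	civilian	Firmicutes	FALSE
Prevotella_15	FBSG	civilian	Bacteroidetes	FALSE
Bacteroidales_88	FBSG	civilian	Bacteroidetes	FALSE
Prevotella_272	FBSG	civilian	Bacteroidetes	FALSE
Bacteria_287	FBSG	civilian	Others	FALSE
Bacteria_469	FBSG	civilian	Others	FALSE
Salinivibrio_60	FBSG	civilian	Others	FALSE
Rothia_64	FBSG	guard	Actinobacteria	FALSE
Rothia_456	FBSG	guard	Actinobacteria	FALSE
Lactobacillales_246	FBSG	guard	Firmicutes	FALSE
Lachnospiraceae_89	FBSG	guard	Firmicutes	FALSE
Peptostreptococcus_4	FBSG	guard	Firmicutes	FALSE
Streptococcus_452	FBSG	guard	Firmicutes	FALSE
Veillonellaceae_445	FBSG	guard	Firmicutes	FALSE
Streptococcus_230	FBSG	guard	Firmicutes	FALSE
Oribacterium_135	FBSG	guard	Firmicutes	FALSE
Prevotella_21	FBSG	guard	Bacteroidetes	FALSE
Prevotella_443	FBSG	guard	Bacteroidetes	FALSE
pallens_179	FBSG	guard	Bacteroidetes	FALSE
Prevotella_30	FBSG	guard	Bacteroidetes	FALSE
Haemophilus_511	FBSG	guard	Others	FALSE
Enterobacter_236	FBSG	guard	Others	FALSE
Haemophilus_16	FBSG	guard	Others	FALSE
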