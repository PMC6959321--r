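name	phylum
Corynebacterium	Actinobacteria
Actinomyces	Actinobacteria
Rothia	Actinobacteria
Streptococcus	Firmicutes
Veillonella	Firmicutes
Veillonellaceae	Firmicutes
Mogibacterium	Firmicutes
Lactobacillales	Firmicutes
Lachnospiraceae	Firmicutes
Peptostreptococcus	Firmicutes
Oribacterium	Firmicutes
Thermophilus	Firmicutes
Capnocytophaga	Bacteroidetes
Prevotella	Bacteroidetes
Bacteroidales	Bacteroidetes
pallens	Bacteroidetes
Fusobacterium	Fusobacteria
Leptotrichia	Fusobacteria
Neisseriaceae	Proteobacteria
Haemophilus	Proteobacteria
Enterobacter	Proteobacteria
Salinivibrio	Proteobacteria
Bacteria	Others
valvarum	Others
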