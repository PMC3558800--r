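PF90001	GO:0004672	protein kinase activity	Gene Ontology	0.92
PF90001	GO:0006468	protein phosphorylation	Gene Ontology	0.88
PF90001	HP:0001250	Seizure	Human Phenotype Ontology	0.41
PF90002	GO:0003700	DNA-binding transcription factor activity	Gene Ontology	0.77
PF90002	MP:0001262	decreased body weight	Mammalian Phenotype Ontology	0.35
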