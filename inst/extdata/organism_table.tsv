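species	tag	phylum	cdk	cyclin
Homo sapiens	Hsa	Vertebrata	20	29
Ciona intestinalis	Cin	Urochordata	10	14
Strongylocentrotus purpuratus	Spu	Echinodermata	11	14
Branchiostoma floridae	Bfl	Cephalochordata	12	16
Drosophila melanogaster	Dme	Arthropoda	11	14
Nematostella vectensis	Nve	Cnidaria	12	16
Trichoplax adhaerens	Tad	Placozoa	14	14
Amphimedon queenslandica	Aqe	Porifera	11	13
Monosiga brevicollis	Mbr	Choanoflagellata	10	8
Salpingoeca rosetta	Sro	Choanoflagellata	6	8
Capsaspora owczarzaki	Cow	Filasterea	9	10
Sphaeroforma arctica	Sar	Ichthyosporea	3	9
Saccharomyces cerevisiae	Sce	Fungi	6	15
Schizosaccharomyces pombe	Spo	Fungi	7	11
Coprinopsis cinerea	Cci	Fungi	7	9
Spizellomyces punctatus	Spn	Fungi	8	8
Thecamonas trahens	Ttr	Apusozoa	7	9
Dictyostelium discoideum	Ddi	Amoebozoa	8	9
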