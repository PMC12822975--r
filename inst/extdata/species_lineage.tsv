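species	lineage
Homo sapiens	placentals
Mus musculus	placentals
Rattus norvegicus	placentals
Sus scrofa	placentals
Bos taurus	placentals
Canis lupus familiaris	placentals
Monodelphis domestica	marsupials
Ornithorhynchus anatinus	monotremes
Gallus gallus	birds
Taeniopygia guttata	birds
Anolis carolinensis	reptiles
Xenopus tropicalis	amphibians
Danio rerio	fish
Oryzias latipes	fish
Takifugu rubripes	fish
Lepisosteus oculatus	fish
Petromyzon marinus	agnathans
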