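taxon_id	parent_id	rank	name
root	.	norank	root
Bacteria	root	superkingdom	Bacteria
Archaea	root	superkingdom	Archaea
Bacteroidetes	Bacteria	phylum	Bacteroidetes
Flavobacteriia	Bacteroidetes	class	Flavobacteriia
Flavobacteriales	Flavobacteriia	order	Flavobacteriales
Flavobacteriaceae	Flavobacteriales	family	Flavobacteriaceae
Polaribacter	Flavobacteriaceae	genus	Polaribacter
Polaribacter_sp	Polaribacter	species	Polaribacter_sp
Owenweeksia	Flavobacteriaceae	genus	Owenweeksia
Owenweeksia_sp	Owenweeksia	species	Owenweeksia_sp
Proteobacteria	Bacteria	phylum	Proteobacteria
Alphaproteobacteria	Proteobacteria	class	Alphaproteobacteria
Pelagibacterales	Alphaproteobacteria	order	Pelagibacterales
Pelagibacteraceae	Pelagibacterales	family	Pelagibacteraceae
Pelagibacter	Pelagibacteraceae	genus	Pelagibacter
Pelagibacter_sp	Pelagibacter	species	Pelagibacter_sp
Planktomarina	Pelagibacteraceae	genus	Planktomarina
Planktomarina_sp	Planktomarina	species	Planktomarina_sp
Gammaproteobacteria	Proteobacteria	class	Gammaproteobacteria
Thiomicrospirales	Gammaproteobacteria	order	Thiomicrospirales
Thioglobaceae	Thiomicrospirales	family	Thioglobaceae
Thioglobus	Thioglobaceae	genus	Thioglobus
Thioglobus_sp	Thioglobus	species	Thioglobus_sp
Thiomicrorhabdus	Thioglobaceae	genus	Thiomicrorhabdus
Thiomicrorhabdus_sp	Thiomicrorhabdus	species	Thiomicrorhabdus_sp
Thaumarchaeota	Archaea	phylum	Thaumarchaeota
Nitrososphaeria	Thaumarchaeota	class	Nitrososphaeria
Nitrosopumilales	Nitrososphaeria	order	Nitrosopumilales
Nitrosopumilaceae	Nitrosopumilales	family	Nitrosopumilaceae
Nitrosopumilus	Nitrosopumilaceae	genus	Nitrosopumilus
Nitrosopumilus_sp	Nitrosopumilus	species	Nitrosopumilus_sp
Nitrosarchaeum	Nitrosopumilaceae	genus	Nitrosarchaeum
Nitrosarchaeum_sp	Nitrosarchaeum	species	Nitrosarchaeum_sp
Actinobacteria	Bacteria	phylum	Actinobacteria
Acidimicrobiia	Actinobacteria	class	Acidimicrobiia
Acidimicrobiales	Acidimicrobiia	order	Acidimicrobiales
Acidimicrobiaceae	Acidimicrobiales	family	Acidimicrobiaceae
Actinomarina	Acidimicrobiaceae	genus	Actinomarina
Actinomarina_sp	Actinomarina	species	Actinomarina_sp
Ilumatobacter	Acidimicrobiaceae	genus	Ilumatobacter
Ilumatobacter_sp	Ilumatobacter	species	Ilumatobacter_sp
Verrucomicrobia	Bacteria	phylum	Verrucomicrobia
Verrucomicrobiae	Verrucomicrobia	class	Verrucomicrobiae
Verrucomicrobiales	Verrucomicrobiae	order	Verrucomicrobiales
Rubritaleaceae	Verrucomicrobiales	family	Rubritaleaceae
Luteolibacter	Rubritaleaceae	genus	Luteolibacter
Luteolibacter_sp	Luteolibacter	species	Luteolibacter_sp
Roseibacillus	Rubritaleaceae	genus	Roseibacillus
Roseibacillus_sp	Roseibacillus	species	Roseibacillus_sp
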