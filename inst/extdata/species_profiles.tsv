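species	common_name	order	lifespan_years	mass_g	assembly_size_gb	cancer_phenotype	lifespan_phenotype	lifespan_source
Heterocephalus glaber	naked mole-rat	Rodentia	31	35	3.042	cancer_resistant	long_lived	printed
Cavia porcellus	guinea pig	Rodentia	12	728	2.723	cancer_prone	short_lived	printed
Mus musculus	house mouse	Rodentia	4	20.5	2.728	cancer_prone	short_lived	printed
Rattus norvegicus	Norway rat	Rodentia	3.8	300	2.648	cancer_prone	short_lived	printed
Myotis myotis	greater mouse-eared bat	Chiroptera	37.1	26.5	2.003	cancer_resistant	long_lived	AnAge
Myotis lucifugus	little brown bat	Chiroptera	34	10	2.035	cancer_resistant	long_lived	AnAge
Rhinolophus ferrumequinum	greater horseshoe bat	Chiroptera	30.5	23	2.075	cancer_resistant	long_lived	AnAge
Rousettus aegyptiacus	Egyptian fruit bat	Chiroptera	22.9	127	1.893	cancer_resistant	long_lived	AnAge
Pteropus vampyrus	large flying fox	Chiroptera	20.9	1000	1.996	cancer_resistant	long_lived	AnAge
Molossus molossus	velvety free-tailed bat	Chiroptera	5.6	12.9	2.319	cancer_resistant	short_lived	printed
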