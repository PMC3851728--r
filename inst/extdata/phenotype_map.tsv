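field	key	value
tissue	retina	retina
tissue	rpe-choroid	rpe_choroid
tissue	rpe choroid	rpe_choroid
tissue	rpe_choroid	rpe_choroid
tissue	choroid	rpe_choroid
region	extramacular	extramacular
region	extra-macular	extramacular
region	macular	macular
region	macula	macular
phenotype	subclinical	MD2
phenotype	pre-amd	MD1
phenotype	md1	MD1
phenotype	md2	MD2
phenotype	ga/cnv	GA_CNV
phenotype	ga cnv	GA_CNV
phenotype	dry	dry
phenotype	geographic atrophy	GA
phenotype	cnv	CNV
phenotype	wet	CNV
phenotype	ga	GA
phenotype	normal	normal
phenotype	control	normal
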