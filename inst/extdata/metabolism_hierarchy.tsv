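level	id	name	parent_id
category	1	Metabolism	
subcategory	1.1	Carbohydrate Metabolism	1
subcategory	1.2	Energy Metabolism	1
subcategory	1.3	Lipid Metabolism	1
subcategory	1.4	Nucleotide Metabolism	1
subcategory	1.5	Amino Acid Metabolism	1
subcategory	1.6	Metabolism of Other Amino Acids	1
subcategory	1.7	Glycan Biosynthesis and Metabolism	1
subcategory	1.8	Metabolism of Cofactors and Vitamins	1
subcategory	1.11	Xenobiotics Biodegradation and Metabolism	1
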