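# sugarcat-registry v1
pathway_id	pathway_name	n_genomes	n_genes
CCM	Central carbon metabolism	19	21
Nag	N-acetylglucosamine, chitin	18	15
Grt	Glycerate	17	3
Bgl	beta-glucosides, cellobiose	9	8
Scr	Sucrose	8	5
Mal	Maltodextrins	14	13
Ara	Arabinose, arabinosides	6	18
Gal	Galactose, galactosides	8	10
Gnt	Gluconate	4	3
Aga	N-acetylgalactosamine	4	8
Man	Mannosides	4	14
Tre	Trehalose	3	6
Xlt	Xylitol	2	6
Rbs	Ribose	2	6
Nan	Sialic acids	1	10
Alg	Alginate	1	6
Mtl	Mannitol	1	5
Unassigned	Unassigned	19	13
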