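mirna	gene
mmu-let7i-5p	Atp2a2
mmu-miR-130a-3p	Atp2a2
mmu-miR-30a-5p	Atp2a2
mmu-miR-465a-5p	Atp2a2
mmu-let7i-5p	Ccr7
mmu-miR-30a-5p	Ccr7
mmu-miR-465a-5p	Ccr7
mmu-let7i-5p	Dapk1
mmu-miR-122-5p	Dapk1
mmu-miR-125b-5p	Dapk1
mmu-miR-26a-5p	Dapk1
mmu-miR-324-5p	Dapk1
mmu-miR-465a-5p	Dapk1
mmu-miR-491-5p	Dapk1
mmu-miR-543-3p	Dapk1
mmu-miR-10a-5p	Egfr
mmu-miR-130a-3p	Egfr
mmu-miR-27a-3p	Egfr
mmu-miR-27b-3p	Egfr
mmu-miR-543-3p	Fos
mmu-miR-122-5p	Foxo1
mmu-miR-130a-3p	Foxo1
mmu-miR-26a-5p	Foxo1
mmu-miR-27a-3p	Foxo1
mmu-miR-27b-3p	Foxo1
mmu-miR-30a-5p	Foxo1
mmu-miR-465a-5p	Foxo1
mmu-miR-491-5p	Foxo1
mmu-miR-543-3p	Foxo1
mmu-miR-122-5p	Gata4
mmu-miR-125b-5p	Gata4
mmu-miR-26a-5p	Gata4
mmu-miR-491-5p	Gata4
mmu-miR-10a-5p	Kcnh3
mmu-miR-125b-5p	Kcnh3
mmu-miR-491-5p	Kcnh3
mmu-miR-130a-3p	Map2k1
mmu-miR-30a-5p	Map2k1
mmu-miR-465a-5p	Map2k1
mmu-let7i-5p	Mapk1
mmu-miR-122-5p	Mapk1
mmu-miR-130a-3p	Mapk1
mmu-miR-26a-5p	Mapk1
mmu-miR-27a-3p	Mapk1
mmu-miR-27b-3p	Mapk1
mmu-miR-30a-5p	Mapk1
mmu-miR-491-5p	Mapk1
mmu-miR-543-3p	Mapk1
mmu-let7i-5p	Mapk9
mmu-miR-10a-5p	Mapk9
mmu-miR-125b-5p	Mapk9
mmu-miR-130a-3p	Mapk9
mmu-miR-27a-3p	Mapk9
mmu-miR-27b-3p	Mapk9
mmu-miR-543-3p	Mapk9
mmu-miR-10a-5p	Mgat3
mmu-miR-125b-5p	Mgat3
mmu-miR-27a-3p	Mgat3
mmu-miR-27b-3p	Mgat3
mmu-miR-324-5p	Mgat3
mmu-let7i-5p	Rnf7
mmu-miR-10a-5p	Rnf7
mmu-miR-27a-3p	Rnf7
mmu-miR-27b-3p	Rnf7
mmu-miR-543-3p	Rnf7
mmu-miR-30a-5p	Vkorc1l1
mmu-miR-465a-5p	Vkorc1l1
mmu-miR-491-5p	Vkorc1l1
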