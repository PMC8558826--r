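receptor	ligand	ligand_kind	molecule	categories	source
ITGB1	MDK	protein		growth_factor_wnt	FANTOM5
SDC4	MDK	protein		growth_factor_wnt	FANTOM5
LRP2	MDK	protein		growth_factor_wnt	FANTOM5
RYK	WNT5A	protein		growth_factor_wnt	FANTOM5
MERTK	GAS6	protein		growth_factor_wnt	FANTOM5
LGR4	NDP	protein		growth_factor_wnt	curated
ACVR2A	BMP4	protein		growth_factor_wnt	FANTOM5
ACVR2B	BMP4	protein		growth_factor_wnt	FANTOM5
ITGB1	VEGFA	protein		growth_factor_wnt	FANTOM5
PDGFRA	PDGFA	protein		growth_factor_wnt	FANTOM5
PDGFRA	PDGFB	protein		growth_factor_wnt	FANTOM5
SDC4	FGF2	protein		growth_factor_wnt	FANTOM5
FGFR4	FGF2	protein		growth_factor_wnt	FANTOM5
CKAP4	DKK1	protein		growth_factor_wnt	curated
TGFBR1	TGFB1	protein		growth_factor_wnt	FANTOM5
SDC2	TGFB1	protein		growth_factor_wnt	FANTOM5
SDC2	HGF	protein		growth_factor_wnt	FANTOM5
CD9	HBEGF	protein		growth_factor_wnt	curated
ADIPOR1	ADIPOQ	protein		growth_factor_wnt	FANTOM5
ADIPOR2	ADIPOQ	protein		growth_factor_wnt	FANTOM5
MAGED1	NGF	protein		growth_factor_wnt	curated
NPR2	NPPC	protein		growth_factor_wnt	curated
CD48	IL18	protein		cytokine_chemokine	curated
ITGB1	CXCL12	protein		cytokine_chemokine	FANTOM5
SDC4	CXCL12	protein		cytokine_chemokine	FANTOM5
AMFR	GPI	protein		cytokine_chemokine	curated
SDC4	CXCL10	protein		cytokine_chemokine	FANTOM5
CSF1R	CSF1	protein		cytokine_chemokine	FANTOM5
SDC4	CCL5	protein		cytokine_chemokine	FANTOM5
IL10RB	IL10	protein		cytokine_chemokine	FANTOM5
IL2RG	IL2	protein		cytokine_chemokine	FANTOM5
TNFRSF6B	TNFSF14	protein		cytokine_chemokine	FANTOM5
TNFRSF6B	TNFSF15	protein		cytokine_chemokine	FANTOM5
TNFRSF6B	FASLG	protein		cytokine_chemokine	FANTOM5
ITGB1	THBS1	protein		juxtacrine_matricellular	FANTOM5
ITGB3	THBS1	protein		juxtacrine_matricellular	FANTOM5
SDC4	THBS1	protein		juxtacrine_matricellular	FANTOM5
CD47	THBS1	protein		juxtacrine_matricellular	FANTOM5
CD36	THBS1	protein		juxtacrine_matricellular	FANTOM5
ITGB1	THBS2	protein		juxtacrine_matricellular	FANTOM5
ITGB3	THBS2	protein		juxtacrine_matricellular	FANTOM5
HHIP	IHH	protein		juxtacrine_matricellular	curated
HHIP	DHH	protein		juxtacrine_matricellular	curated
ITGB3	CCN1	protein		juxtacrine_matricellular	curated
ITGB1	ADAM9	protein		juxtacrine_matricellular	FANTOM5
ITGB1	ADAM12	protein		juxtacrine_matricellular	FANTOM5
SDC4	ADAM12	protein		juxtacrine_matricellular	FANTOM5
ITGB1	ADAM15	protein		juxtacrine_matricellular	FANTOM5
ITGB3	ADAM15	protein		juxtacrine_matricellular	FANTOM5
ITGB1	ADAM17	protein		juxtacrine_matricellular	FANTOM5
FZD3	MYOC3	protein		juxtacrine_matricellular	curated
CXADR	JAML	protein		juxtacrine_matricellular	curated
DCBLD2	SEMA4B	protein		juxtacrine_matricellular	curated
ITGB1	CD14	protein		juxtacrine_matricellular	FANTOM5
PTPRA	NCAM1	protein		juxtacrine_matricellular	curated
PECAM1	EFNB2	protein		juxtacrine_matricellular	FANTOM5
CD9	ADAM2	protein		juxtacrine_matricellular	curated
CD81	C3	protein		juxtacrine_matricellular	curated
CD81	GPC3	protein		juxtacrine_matricellular	curated
RPSA	LAMB1	protein		juxtacrine_matricellular	curated
CHRNB2	ACHE	synthesis_enzyme_proxy	acetylcholine	small_molecule	recorded as assigned in source atlas
GPRC5C	RDH10	synthesis_enzyme_proxy	retinoic acid	small_molecule	curated
RXRB	RDH10	synthesis_enzyme_proxy	retinoic acid	small_molecule	curated
PGRMC1	HSD3B1	synthesis_enzyme_proxy	progesterone	small_molecule	curated
LPAR1	ENPP2	synthesis_enzyme_proxy	lysophosphatidic acid	small_molecule	curated
LPAR2	ENPP2	synthesis_enzyme_proxy	lysophosphatidic acid	small_molecule	curated
LPAR6	ENPP2	synthesis_enzyme_proxy	lysophosphatidic acid	small_molecule	curated
GPR34	ENPP2	synthesis_enzyme_proxy	lysophosphatidic acid	small_molecule	curated
HRH1	HDC	synthesis_enzyme_proxy	histamine	small_molecule	curated
GPBAR1	CYP7A1	synthesis_enzyme_proxy	bile acids	small_molecule	curated
NR1H2	CH25H	synthesis_enzyme_proxy	oxysterols	small_molecule	curated
ESRRG	CYP19A1	synthesis_enzyme_proxy	estradiol	small_molecule	curated
CNR2	NAPEPLD	synthesis_enzyme_proxy	cannabinoids	small_molecule	curated
ADRB2	TH	synthesis_enzyme_proxy	catecholamines	small_molecule	curated
HTR2B	TPH1	synthesis_enzyme_proxy	serotonin	small_molecule	curated
PTGFR	AKR1B1	synthesis_enzyme_proxy	prostaglandin F2alpha	small_molecule	curated
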