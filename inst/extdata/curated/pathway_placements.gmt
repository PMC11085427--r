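VEGFA-VEGFR2 Signaling Pathway	WikiPathways|vascular	CSK	MKNK1	MYO6	PTPRJ	SMARCA2	TNXB
Regulation of actin cytoskeleton	both|vascular	BRK1	CSK	GNA13	SOS2
Adherens junction	KEGG|vascular	PTPRJ	TCF7L2	YES1
Angiopoietin Like Protein 8 Regulatory Pathway	WikiPathways|vascular	LPL	PRKAG2	SOS2
ECM-receptor interaction	KEGG|vascular	NPNT	TNXB	VTN
Focal adhesion	KEGG|vascular	SOS2	TNXB	VTN
Apelin signaling pathway	KEGG|vascular	GNA13	PRKAG2
Cholesterol metabolism	KEGG|vascular	LDLR	LPL
Composition of Lipid Particles	WikiPathways|vascular	LDLR	LPL
Fluid shear stress and atherosclerosis	KEGG|vascular	BMPR1B	GSTA4
Glycerolipid metabolism	KEGG|vascular	ALDH2	LPL
Metabolic pathway of LDL, HDL and TG, including diseases	WikiPathways|vascular	LDLR	LPL
Platelet activation	KEGG|vascular	GNA13	LYN
Statin Pathway	WikiPathways|vascular	LDLR	LPL
Chemokine signaling pathway	both|inflammation	CSK	LYN	SOS2
Cytokine-cytokine receptor interaction	KEGG|inflammation	BMPR1B	GDF10	LTB
NF-kappa B signaling pathway	both|inflammation	LTB	LYN	TAB2
Regulation of toll-like receptor signaling pathway	WikiPathways|inflammation	IRF5	SARM1	TAB2
B cell receptor signaling pathway	KEGG|inflammation	LYN	SOS2
Interleukin-11 Signaling Pathway	WikiPathways|inflammation	FES	YES1
Natural killer cell mediated cytotoxicity	KEGG|inflammation	NCR3	SOS2
Structural Pathway of Interleukin 1 (IL-1)	WikiPathways|inflammation	MKNK1	TAB2
TNF signaling pathway	KEGG|inflammation	DAB2IP	TAB2
Toll-like receptor signaling pathway	both|inflammation	IRF5	TAB2
MAPK signaling pathway	both|signaling	MKNK1	SOS2	STK3	TAB2
PI3K-Akt signaling pathway	both|signaling	MCL1	SOS2	TNXB	VTN
EGF/EGFR Signaling Pathway	WikiPathways|signaling	CSK	SOS2	TWIST1
Insulin signaling pathway	KEGG|signaling	MKNK1	PRKAG2	SOS2
Sterol Regulatory Element-Binding Proteins (SREBP) signalling	WikiPathways|signaling	LDLR	LPL	PRKAG2
cGMP-PKG signaling pathway	KEGG|signaling	ATP2B1	GNA13
FoxO signaling pathway	KEGG|signaling	PRKAG2	SOS2
Jak-STAT signaling pathway	KEGG|signaling	MCL1	SOS2
Phospholipase D signaling pathway	KEGG|signaling	GNA13	SOS2
Wnt Signaling Pathway and Pluripotency	WikiPathways|signaling	LDLR	TCF7L2
NRF2 pathway	WikiPathways|antioxidant	GSTA4	SLC39A8
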