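STUDY ACCESSION	DISEASE/TRAIT	SNPS	MAPPED_GENE	P-VALUE
GCST011141	Hypertension	rs671	ALDH2	1e-12
GCST001231	Atherosclerosis	rs445925	APOE (also APOC1)	2e-10
GCST002627	Hypertension	rs10745332	CAPZA1	3e-9
GCST007707	Hypertension	rs17030613	CAPZA1	1e-8
GCST007707	Hypertension	rs62524579	CYP11B2 (also LY6E-DT)	4e-9
GCST007707	Hypertension	rs12679242	CYP11B2	5e-9
GCST007707	Hypertension	rs6418	CYP11B2 (also GML)	2e-9
GCST011141	Hypertension	rs1799998	CYP11B2 (also LY6E-DT)	6e-10
GCST011952	Hypertension	rs12941507	GNA13 (also AMZ2P1)	1e-9
GCST011953	Hypertension	rs12941507	GNA13 (also AMZ2P1)	1e-9
GCST008474	Atherosclerosis	rs4722172	IL6 (also MTCYBP42)	3e-8
GCST006023	Hypertension	rs4728142	IRF5 (also KCP)	7e-11
GCST001231	Atherosclerosis	rs6511720	LDLR	1e-15
GCST008474	Atherosclerosis	rs138294113	LDLR (also SMARCA4)	2e-8
GCST008474	Atherosclerosis	rs322	LPL	4e-10
GCST007707	Hypertension	rs1973765	LSP1	1e-9
GCST007707	Hypertension	rs569550	LSP1	2e-9
GCST007707	Hypertension	rs661348	LSP1	3e-9
GCST007707	Hypertension	rs4980389	LSP1	4e-9
GCST010477	Hypertension	rs139537100	MKNK1 (also MOB3C)	5e-8
GCST008474	Atherosclerosis	rs566125	MMP3	6e-9
GCST009685	Hypertension	rs17367504	MTHFR	1e-13
GCST001085	Hypertension	rs3798440; A x rs9350602; C	no mapped genes x MYO6	2e-8
GCST010477	Hypertension	rs2515920	NCR3 (also UQCRHP1)	8e-9
GCST008403	Arterial stiffness	rs17036160	PPARG	9e-9
GCST90000064	Hypertension	rs704	SARM1 (also VTN)	1e-10
GCST007846	Arterial stiffness	rs17478227	TCF20	2e-9
GCST008474	Atherosclerosis	rs7903146	TCF7L2	3e-11
GCST010477	Hypertension	rs769177	TNF (also LTB)	4e-9
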