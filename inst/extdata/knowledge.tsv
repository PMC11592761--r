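gene	syndrome	inheritance	truncation_is_mechanism	mesenchymal_association	surveillance_exists
BRCA1	Hereditary breast and ovarian cancer	dominant	TRUE	none	TRUE
BRCA2	Hereditary breast and ovarian cancer	dominant	TRUE	none	TRUE
FLCN	Birt-Hogg-Dube syndrome	dominant	TRUE	suggested	TRUE
SDHAF2	Hereditary paraganglioma-pheochromocytoma	dominant	TRUE	none	FALSE
SDHA	Hereditary paraganglioma-pheochromocytoma	dominant	TRUE	known	TRUE
SDHB	Hereditary paraganglioma-pheochromocytoma	dominant	TRUE	known	TRUE
SDHC	Hereditary paraganglioma-pheochromocytoma	dominant	TRUE	known	TRUE
ATM	ATM-related cancer risk	dominant	TRUE	none	FALSE
MLH1	Lynch syndrome	dominant	TRUE	semi	TRUE
MSH2	Lynch syndrome	dominant	TRUE	semi	TRUE
MSH6	Lynch syndrome	dominant	TRUE	semi	TRUE
PMS2	Lynch syndrome	dominant	TRUE	semi	TRUE
CHEK2	CHEK2-related cancer risk	dominant	TRUE	none	TRUE
RB1	Hereditary retinoblastoma	dominant	TRUE	known	TRUE
CDC73	Hyperparathyroidism-jaw tumor syndrome	dominant	TRUE	none	TRUE
MITF	MITF-related melanoma and renal cell carcinoma risk	dominant	FALSE	none	FALSE
NF1	Neurofibromatosis type 1	dominant	TRUE	known	TRUE
EXT1	Hereditary multiple osteochondromas	dominant	TRUE	known	FALSE
EXT2	Hereditary multiple osteochondromas	dominant	TRUE	known	TRUE
TP53	Heritable TP53-related cancer syndrome	dominant	TRUE	known	TRUE
ATR	ATR-related cancer risk	dominant	TRUE	none	FALSE
MRE11	MRE11-related cancer risk	dominant	TRUE	none	FALSE
DDX41	DDX41-related hematologic malignancy risk	dominant	TRUE	none	FALSE
BRIP1	BRIP1-related ovarian cancer risk	dominant	TRUE	none	FALSE
KCNQ1	Long QT syndrome	dominant	TRUE	none	FALSE
POLG	Mitochondrial DNA depletion syndrome	recessive	TRUE	none	FALSE
MUTYH	MUTYH-associated polyposis	recessive	TRUE	none	TRUE
NBN	NBN-related cancer risk	recessive	TRUE	none	FALSE
APC	Familial adenomatous polyposis	dominant	TRUE	suggested	TRUE
PALB2	PALB2-related cancer risk	dominant	TRUE	none	TRUE
PTEN	PTEN hamartoma tumor syndrome	dominant	TRUE	suggested	TRUE
VHL	Von Hippel-Lindau syndrome	dominant	TRUE	none	TRUE
BAP1	BAP1 tumor predisposition syndrome	dominant	TRUE	suggested	TRUE
BARD1	BARD1-related cancer risk	dominant	TRUE	none	FALSE
BLM	Bloom syndrome	recessive	TRUE	none	FALSE
BMPR1A	Juvenile polyposis syndrome	dominant	TRUE	none	TRUE
CDH1	Hereditary diffuse gastric cancer	dominant	TRUE	none	TRUE
CDK4	CDK4-related melanoma risk	dominant	FALSE	none	FALSE
CDKN2A	Familial melanoma	dominant	TRUE	none	TRUE
DICER1	DICER1 syndrome	dominant	TRUE	suggested	TRUE
EPCAM	Lynch syndrome (EPCAM-related)	dominant	TRUE	semi	TRUE
FANCA	Fanconi anemia	recessive	TRUE	none	FALSE
FH	Hereditary leiomyomatosis and renal cell cancer	dominant	TRUE	known	TRUE
KIT	Familial GIST syndrome	dominant	FALSE	known	TRUE
MEN1	Multiple endocrine neoplasia type 1	dominant	TRUE	none	TRUE
NF2	NF2-related schwannomatosis	dominant	TRUE	suggested	TRUE
PDGFRA	Familial GIST syndrome	dominant	FALSE	known	TRUE
POLD1	Polymerase proofreading-associated polyposis	dominant	FALSE	none	TRUE
POLE	Polymerase proofreading-associated polyposis	dominant	FALSE	none	TRUE
PTCH1	Gorlin syndrome	dominant	TRUE	suggested	TRUE
RAD51C	RAD51C-related ovarian cancer risk	dominant	TRUE	none	FALSE
RAD51D	RAD51D-related ovarian cancer risk	dominant	TRUE	none	FALSE
RET	Multiple endocrine neoplasia type 2	dominant	FALSE	none	TRUE
SDHD	Hereditary paraganglioma-pheochromocytoma	dominant	TRUE	known	TRUE
SMARCA4	SMARCA4-related rhabdoid tumor predisposition	dominant	TRUE	suggested	TRUE
SMARCB1	Rhabdoid tumor predisposition syndrome	dominant	TRUE	known	TRUE
STK11	Peutz-Jeghers syndrome	dominant	TRUE	none	TRUE
SUFU	SUFU-related medulloblastoma predisposition	dominant	TRUE	none	FALSE
TSC1	Tuberous sclerosis complex	dominant	TRUE	suggested	TRUE
TSC2	Tuberous sclerosis complex	dominant	TRUE	suggested	TRUE
WRN	Werner syndrome	recessive	TRUE	suggested	FALSE
WT1	WT1-related Wilms tumor predisposition	dominant	TRUE	none	TRUE
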