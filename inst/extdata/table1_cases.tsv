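case_no	diagnosis	gene	transcript	hgvs_c	hgvs_p	clinical_impact	pedigree	previous_treatment	comorbidity	syndrome_known	fulfils_criteria	second_hit
40	Leiomyoma	BRCA1	NM_007294	c.406del	p.Arg136AspfsTer27	Clinical action	No known cancer	No	OvC 55 y	Yes	Yes	No second hit
52	Osteosarcoma, parosteal	FLCN	NM_144606	c.779+1G>T	NA	Clinical action	No known cancer	No	No	No	No	No second hit
62	GIST	SDHAF2	NM_017841	c.37-1G>C	NA	Risk factor	No known cancer	No	HT	No	No	No second hit
63	GIST, wild-type	SDHA	NM_004168	c.223C>T	p.Arg75Ter	Clinical action	No known cancer	No	DCMP, dementia	No	No	SNV: SDHA, NM_004168, c.896G>A, p.Gly299Asp
67	Angiosarcoma	ATM	NM_000051	c.7570G>C	p.Ala2524Pro	Risk factor	No known cancer	No	HT	No	No	SNV: ATM, NM_000051, c.5188C>T, p.Arg1730Ter
76	Pleomorphic liposarcoma	MLH1	NM_000249	c.546-2A>G	NA	Clinical action	No known cancer	No	CRC 52 y, kidney failure, HT	No	No	Deletion MLH1
95	Liposarcoma, dedifferentiated	CHEK2	NM_001005735	c.1229del	p.Thr410MetfsTer15	Clinical action	No known cancer	RT, chemo breast	BrC 65, HT	No	No	No second hit
101	Leiomyosarcoma	RB1	NM_000321	c.1981C>T	p.Arg661Trp	Clinical action	Brother's son suspected RB 4y, mother UtC 50y.	No	No	No	No	Deletion RB1
111	Leiomyosarcoma	RB1	NM_000321	c.184C>T	p.Gln62Ter	Clinical action	No known cancer	RT OS	RB bilateral 6 months, OS legs multiple during childhood, endometriosis	Yes	Yes	Deletion RB1
115	Adenosarcoma, sarcomatous overgrowth	CDC73	NM_024529	c.664C>T	p.Arg222Ter	Clinical action	Mother and sister LuC	No	Hypothyreosis, lung embolus	No	No	SNV: CDC73, NM_024529, c.25C>T, p.Arg9Ter
139	Radiation-induced sarcoma	MSH6	NM_000179	c.2851_2858del	p.Leu951IlefsTer12	Clinical action	Mother OvC, son testis cancer, daughter BC, daughter CxC	RT, chemo breast	BrC 44 y, UtC 48 y	Yes	Yes	No verified second hit
144	GIST	MITF	NM_198159	c.1255G>A	p.Glu419Lys	Risk factor	No known cancer	No	UtC 75	No	No	No second hit
168	MPNST	NF1	NM_000267	c.1721+3A>C	NA	Clinical action	Sister brain tumor	No	GIST small intestine	Yes	Yes	SNV: NF1, NM_000267, c.565A>T, p.Lys189Ter
207	DFSP, fibrosarcoma	EXT1	NM_000127	c.1018C>T	p.Arg340Cys	Risk factor	No known cancer	No	No	No	No	No second hit
208	Leiomyosarcoma	TP53	NM_001126112	c.503del	p.His168ProfsTer2	Clinical action	No known cancer	Interferone	OS 16 y, LMS 35 y	No	Yes	Deletion TP53
231	Liposarcoma (DDLPS)	ATR	NM_001184	c.6836dup	p.Asn2279LysfsTer4	Risk factor	No known cancer	No	No	No	No	No second hit
265	Leiomyoma	MRE11	NM_005591	c.1090C>T	p.Arg364Ter	Risk factor	No known cancer	No	No	No	No	No second hit
295	Secondary peripheral chondrosarcoma	EXT2	NM_000401	c.441C>G	p.Tyr147Ter	Clinical action	No known cancer	No	CHS	Yes	Yes	Deletion EXT2
306	MPNST	NF1	NM_000267	c.4974_4977del	p.Tyr1659ThrfsTer17	Clinical action	No known cancer	RT brain	Intracranial sarcoma 23 y, Scwannoma 24 y, Cafe-au-lait spots	Yes	Yes	SNV: NF1, NM_000267, c.365_371del, p.His122LeufsTer41
311	Synovial chondromatosis	CHEK2	NM_001005735	c.1229del	p.Thr410MetfsTer15	Clinical action	Sister breast cancer	RT, chemo breast, Tamoxifene	BrC 59 y	No	Yes	No second hit
329	Low-grade parosteal OS	CHEK2	NM_001005735	c.1229del	p.Thr410MetfsTer15	Risk factor	No known cancer	No	No	No	No	No second hit
339	Soft tissue sarcoma paravertebral	MSH6	NM_000179	c.3261del	p.Phe1088SerfsTer2	Clinical action	Sister OvC, mother BC 59y + UrC 59y + CRC 67y + UtC 53y, maternal grandmother UtC	Chemo	CRC 54 y	Yes	Yes	NA
353	Leiomyosarcoma	DDX41	NM_016222	c.415_418dup	p.Asp140GlyfsTer2	Risk factor	Father CRC	RT, chemo kidney	Wilm's tumor kidney and lung, cholecystectomy, myoma	No	No	No second hit
364	GIST, wild-type	NF1	NM_000267	c.6792C>A	p.Tyr2264Ter	Clinical action	Son molecularly verified NF1, no known cancer.	No	Cafe-au-lait spots	Yes	Yes	SNV: NF1, NM_000267, c.3723_3730dup, p.Val1244GlufsTer25
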