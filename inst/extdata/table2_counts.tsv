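category	n_no_finding	pct_no_finding	n_germline_finding	pct_germline_finding
soft_tissue_sarcoma_high	120	42	11	46
soft_tissue_sarcoma_low	33	11	1	4
soft_tissue_benign	40	14	1	4
bone_sarcoma_high	13	5	0	0
bone_sarcoma_low	7	2	3	13
bone_benign	5	2	0	0
gist	36	13	4	17
gynaecological_tract	34	12	4	17
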