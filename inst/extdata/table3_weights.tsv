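category	description	weight
gtex_resp_eqtl	GTEX respiratory relevant cell/tissue eQTL (P < 0.05)	1
gtex_blood_eqtl	GTEX blood eQTL (P < 0.05)	1
gtex_resp_sqtl	GTEX respiratory relevant cell/tissue sQTL (P < 0.05)	1
gtex_blood_sqtl	GTEX blood sQTL (P < 0.05)	1
otg_eqtl_resp	OTG eQTL resp (P < 0.05)	1
otg_eqtl_blood	OTG eQTL blood (P < 0.05)	1
otg_v2g	OTG V2G score (presence of)	1
otg_coloc	OTG co-localization study (H4 > 0.8)	1
haploreg_eqtl	HaploReg eQTL (P < 0.05)	1
functional_variant_ld	Functional variant (presence of in an LD r2 > 0.1)	1
ub_brush_eqtl	UBIOPRED brush eQTL (P < 0.05)	2
ub_biopsy_eqtl	UBIOPRED biopsy eQTL (P < 0.05)	2
ub_nasal_eqtl	UBIOPRED nasal eQTL (P < 0.05)	2
literature	Literature association (presence of)	1
total_possible	Total possible score	16
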