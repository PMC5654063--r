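# Literature-derived compendium of 23 conserved, site-selectively A-to-I
# edited recoding sites in mammals: reported adult-tissue editing levels and
# published adjacent-stem (EIE) annotations. Multi-EIE rows hold
# comma-separated metric lists. ND = not determined in the source material.
# 5'/3' side marks that could not be verified are flagged ambiguous_side.
substrate	edit_site	percent_editing	conserved_adjacent_stem	stable_adjacent_stem	eie_length_nt	eie_bp	eie_distance_nt	eie_5p	eie_3p	ambiguous_side
GluA2	Q/R	100	Yes	Yes	102	43	45	no	yes	FALSE
Gabra3	I/M	92	Yes	Yes	149	54	143	no	yes	FALSE
GluA3	R/G	91	Yes	Yes	81	32	220	ND	ND	TRUE
FLNB	Q/R	90	No	ND	ND	ND	ND	ND	ND	FALSE
Htr2c	I/V	85	Yes	Yes	64	27	159	ND	ND	TRUE
GluK2	Q/R	83	Yes	Yes	129,60	42,25	48,32	yes	yes	FALSE
ADAR2	+24	82	Yes	Yes	86	37	60	ND	ND	TRUE
Cyfip2	K/E	75	Yes	Yes	116	47	138	ND	ND	TRUE
GluA2	R/G	72	Yes	Yes	79	30	230	ND	ND	TRUE
GluK1	Q/R	62	Yes	Yes	73	27	70	ND	ND	TRUE
BLCAP	Y/C	50	Yes	Yes	71,59,64	33,26,28	37,90,123	ND	ND	TRUE
IGFBP7	K/E	45	No	ND	ND	ND	ND	ND	ND	FALSE
FLNA	Q/R	43	Yes	Yes	105	36	38	ND	ND	TRUE
Nova1	S/G	30	No	ND	ND	ND	ND	ND	ND	FALSE
KCNA1	I/V	25	No	ND	ND	ND	ND	ND	ND	FALSE
PLCH2	R/G	20	No	ND	ND	ND	ND	ND	ND	FALSE
TMEM63B	Q/R	20	No	ND	ND	ND	ND	ND	ND	FALSE
CCNI	R/G	15	No	ND	ND	ND	ND	ND	ND	FALSE
Azin1	S/G	10	No	ND	ND	ND	ND	ND	ND	FALSE
Copa	I/V	10	No	ND	ND	ND	ND	ND	ND	FALSE
GPATCH8	K/R	10	No	ND	ND	ND	ND	ND	ND	FALSE
NCSTN	S/G	7	No	ND	ND	ND	ND	ND	ND	FALSE
OSGEP	I/M	7	No	ND	ND	ND	ND	ND	ND	FALSE
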