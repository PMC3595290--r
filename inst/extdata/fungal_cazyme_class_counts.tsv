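genome	family	count	lineage
V_volvacea	GH	191	basidiomycete
V_volvacea	GT	44	basidiomycete
V_volvacea	PL	19	basidiomycete
V_volvacea	CE	31	basidiomycete
S_commune	GH	240	basidiomycete
S_commune	GT	75	basidiomycete
S_commune	PL	16	basidiomycete
S_commune	CE	30	basidiomycete
P_chrysosporium	GH	181	basidiomycete
P_chrysosporium	GT	66	basidiomycete
P_chrysosporium	PL	4	basidiomycete
P_chrysosporium	CE	20	basidiomycete
P_placenta	GH	124	basidiomycete
P_placenta	GT	51	basidiomycete
P_placenta	PL	4	basidiomycete
P_placenta	CE	13	basidiomycete
C_cinerea	GH	211	basidiomycete
C_cinerea	GT	71	basidiomycete
C_cinerea	PL	13	basidiomycete
C_cinerea	CE	54	basidiomycete
L_bicolor	GH	163	basidiomycete
L_bicolor	GT	88	basidiomycete
L_bicolor	PL	7	basidiomycete
L_bicolor	CE	20	basidiomycete
C_neoformans	GH	75	basidiomycete
C_neoformans	GT	64	basidiomycete
C_neoformans	PL	3	basidiomycete
C_neoformans	CE	8	basidiomycete
U_maydis	GH	101	basidiomycete
U_maydis	GT	64	basidiomycete
U_maydis	PL	1	basidiomycete
U_maydis	CE	19	basidiomycete
S_cerevisiae	GH	46	ascomycete
S_cerevisiae	GT	68	ascomycete
S_cerevisiae	PL	0	ascomycete
S_cerevisiae	CE	3	ascomycete
A_niger	GH	256	ascomycete
A_niger	GT	123	ascomycete
A_niger	PL	8	ascomycete
A_niger	CE	25	ascomycete
N_crassa	GH	173	ascomycete
N_crassa	GT	76	ascomycete
N_crassa	PL	4	ascomycete
N_crassa	CE	23	ascomycete
T_melanosporum	GH	91	ascomycete
T_melanosporum	GT	96	ascomycete
T_melanosporum	PL	3	ascomycete
T_melanosporum	CE	14	ascomycete
P_indica	GH	225	ascomycete
P_indica	GT	73	ascomycete
P_indica	PL	16	ascomycete
P_indica	CE	45	ascomycete
P_chrysogenum	GH	223	ascomycete
P_chrysogenum	GT	103	ascomycete
P_chrysogenum	PL	9	ascomycete
P_chrysogenum	CE	22	ascomycete
T_reesei	GH	200	ascomycete
T_reesei	GT	103	ascomycete
T_reesei	PL	3	ascomycete
T_reesei	CE	16	ascomycete
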