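# WHO DDD registry for the four licensed NOACs (oral anticoagulants), v1.
# Columns: NAME, ATC, BNF, DDD_MG, STRENGTHS_MG (semicolon-separated mg per unit).
NAME	ATC	BNF	DDD_MG	STRENGTHS_MG
Apixaban	B01AF02	0208020Z0	10	2.5;5
Dabigatran etexilate	B01AE07	0208020X0	300	75;110;150
Edoxaban	B01AF03	0208020AA	60	30;60
Rivaroxaban	B01AF01	0208020Y0	20	2.5;10;15;20
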