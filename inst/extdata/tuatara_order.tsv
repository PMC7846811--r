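name	strand	copy_index	pseudo
trnF	heavy	1	FALSE
rrnS	heavy	1	FALSE
trnV	heavy	1	FALSE
rrnL	heavy	1	FALSE
trnL(UUR)	heavy	1	FALSE
ND1	heavy	1	FALSE
trnI	heavy	1	FALSE
trnQ	light	1	FALSE
trnM	heavy	1	FALSE
ND2	heavy	1	FALSE
trnW	heavy	1	FALSE
trnA	light	1	FALSE
trnN	light	1	FALSE
trnC	light	1	FALSE
trnY	light	1	FALSE
COI	heavy	1	FALSE
trnS(UCN)	light	1	FALSE
trnD	heavy	1	FALSE
COII	heavy	1	FALSE
trnK	heavy	1	FALSE
trnK	heavy	2	TRUE
ATP8	heavy	1	FALSE
ATP6	heavy	1	FALSE
COIII	heavy	1	FALSE
trnG	heavy	1	FALSE
ND3	heavy	1	FALSE
trnR	heavy	1	FALSE
ND4L	heavy	1	FALSE
ND4	heavy	1	FALSE
ND6	light	1	FALSE
trnE	light	1	FALSE
NC1	heavy	1	FALSE
trnL(CUN)	heavy	1	FALSE
ND5	heavy	1	FALSE
trnT	heavy	1	FALSE
trnH	heavy	1	FALSE
NC2	heavy	1	FALSE
trnL(CUN)	heavy	2	FALSE
Cytb	heavy	1	FALSE
trnP	light	1	FALSE
trnS(AGY)	heavy	1	FALSE
NC3	heavy	1	FALSE
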