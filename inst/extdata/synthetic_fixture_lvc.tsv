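word	in_lvc
w01	1
w02	1
w03	1
w04	1
w05	1
w06	1
w07	1
w08	1
w09	1
w10	1
w11	0
w12	0
w13	0
w14	0
w15	0
w16	0
w17	0
w18	0
w19	0
w20	0
w21	0
w22	0
w23	0
w24	0
w25	0
w26	0
w27	0
w28	0
w29	0
w30	0
w31	0
w32	0
w33	0
w34	0
w35	0
w36	0
w37	0
w38	0
w39	0
w40	0
w41	0
w42	0
w43	0
w44	0
w45	0
w46	0
w47	0
w48	0
w49	0
w50	0
w51	0
w52	0
w53	0
w54	0
w55	0
w56	0
w57	0
w58	0
w59	0
w60	0
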