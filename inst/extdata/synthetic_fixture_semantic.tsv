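w01	w02
w01	w04
w01	w10
w02	w03
w02	w06
w03	w04
w03	w08
w04	w05
w05	w06
w05	w09
w06	w07
w07	w08
w07	w10
w08	w09
w09	w10
w11	w12
w12	w13
w13	w14
w14	w15
w15	w16
w16	w17
w17	w18
w18	w19
w19	w20
w20	w21
w21	w22
w22	w23
w23	w24
w24	w25
w25	w26
w26	w27
w27	w28
w28	w29
w29	w30
w30	w31
w31	w32
w32	w33
w33	w34
w34	w35
w35	w36
w36	w37
w37	w38
w38	w39
w39	w40
w40	w41
w41	w42
w42	w43
w43	w44
w44	w45
w45	w46
w46	w47
w47	w48
w48	w49
w49	w50
w50	w51
w51	w52
w52	w53
w53	w54
w54	w55
w55	w56
w56	w57
w57	w58
w58	w59
w59	w60
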