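w01	w03
w01	w10
w01	w11
w02	w04
w02	w09
w02	w12
w03	w05
w04	w06
w05	w07
w06	w08
w07	w09
w08	w10
w11	w13
w12	w14
w13	w15
w14	w16
w15	w17
w16	w18
w17	w19
w18	w20
w19	w21
w20	w22
w21	w23
w22	w24
w23	w25
w24	w26
w25	w27
w26	w28
w27	w29
w28	w30
w29	w31
w30	w32
w31	w33
w32	w34
w33	w35
w34	w36
w35	w37
w36	w38
w37	w39
w38	w40
w39	w41
w40	w42
w41	w43
w42	w44
w43	w45
w44	w46
w45	w47
w46	w48
w47	w49
w48	w50
w49	w51
w50	w52
w51	w53
w52	w54
w53	w55
w54	w56
w55	w57
w56	w58
w57	w59
w58	w60
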