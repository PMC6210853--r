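pair	cells	printed_p
ctnnb1_sex	28,62;3,32	0.0088
ctnnb1_afp	4,42;27,52	0.0015
ctnnb1_vascular	9,49;22,43	0.0194
ctnnb1_differentiation	16,20;15,71	0.0018
tp53_vascular	19,39;7,58	0.0029
tp53_differentiation	3,33;23,63	0.0235
tert_hcv	61,16;24,24	0.0007
tert_nbnc	10,11;75,29	0.0282
hyper_hcv	55,22;26,22	0.0494
hypo_afp	30,16;37,42	0.0469
hypo_vascular	37,21;28,37	0.0216
fal_vascular	39,19;27,38	0.0043
fal_afp	38,8;29,50	<0.0001
fal_differentiation	14,22;51,35	0.0393
subclass_hcv	10,15,25,27;17,6,16,9	0.0149
subclass_afp	14,4,23,5;13,17,18,31	0.0002
subclass_vascular	17,5,25,11;10,16,14,25	0.0013
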