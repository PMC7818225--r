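# erpmass montage: label	x	y	z (unit sphere)
# eog: VEOGU VEOGL HEOGL HEOGR
AF7	-0.55901699437494745	0.76942088429381339	0.30901699437494745
Fp1	-0.29389262614623657	0.90450849718747373	0.30901699437494751
Fpz	0	0.95105651629515364	0.30901699437494751
Fp2	0.29389262614623657	0.90450849718747373	0.30901699437494751
AF8	0.55901699437494745	0.76942088429381339	0.30901699437494745
AF3	-0.29429201708607267	0.83096161983033445	0.47211756485896322
AFz	0	0.80901699437494745	0.58778525229247314
AF4	0.29429201708607267	0.83096161983033445	0.47211756485896322
F7	-0.76942088429381339	0.55901699437494745	0.30901699437494745
F5	-0.61873127286755869	0.61975269610850781	0.48278173913470096
F3	-0.43302742917386172	0.64541636285449455	0.62922568617527974
F1	-0.2228184026194425	0.6345556781910896	0.74006151820613286
Fz	0	0.58778525229247314	0.80901699437494745
F2	0.2228184026194425	0.6345556781910896	0.74006151820613286
F4	0.43302742917386172	0.64541636285449455	0.62922568617527974
F6	0.61873127286755869	0.61975269610850781	0.48278173913470096
F8	0.76942088429381339	0.55901699437494745	0.30901699437494745
FT7	-0.90450849718747373	0.29389262614623662	0.30901699437494751
FC5	-0.75646880044390974	0.34279810573147618	0.5569958820869898
FC3	-0.54352330410984095	0.36229115596397132	0.75718395136176186
FC1	-0.28394295035849249	0.35069925312423006	0.89240486036317734
FCz	0	0.30901699437494745	0.95105651629515364
FC2	0.28394295035849249	0.35069925312423006	0.89240486036317734
FC4	0.54352330410984095	0.36229115596397132	0.75718395136176186
FC6	0.75646880044390974	0.34279810573147618	0.5569958820869898
FT8	0.90450849718747373	0.29389262614623662	0.30901699437494751
T7	-0.95105651629515364	5.823541592445463e-17	0.30901699437494751
C5	-0.80901699437494745	4.9538003630854586e-17	0.58778525229247314
C3	-0.58778525229247314	3.5991466390299838e-17	0.80901699437494745
C1	-0.3090169943749474	1.892183365217075e-17	0.95105651629515364
Cz	0	0	1
C2	0.3090169943749474	1.892183365217075e-17	0.95105651629515364
C4	0.58778525229247314	3.5991466390299838e-17	0.80901699437494745
C6	0.80901699437494745	4.9538003630854586e-17	0.58778525229247314
T8	0.95105651629515364	5.823541592445463e-17	0.30901699437494751
TP7	-0.90450849718747373	-0.29389262614623646	0.30901699437494745
CP5	-0.75646880044390985	-0.34279810573147612	0.55699588208698991
CP3	-0.54352330410984107	-0.36229115596397121	0.75718395136176175
CP1	-0.28394295035849237	-0.35069925312423	0.89240486036317734
CPz	3.7843667304341506e-17	-0.30901699437494745	0.95105651629515364
CP2	0.2839429503584926	-0.35069925312423	0.89240486036317734
CP4	0.54352330410984118	-0.36229115596397121	0.75718395136176175
CP6	0.75646880044390985	-0.34279810573147612	0.5569958820869898
TP8	0.90450849718747373	-0.29389262614623646	0.30901699437494745
P7	-0.7694208842938135	-0.55901699437494745	0.30901699437494751
P5	-0.61873127286755869	-0.61975269610850769	0.48278173913470102
P3	-0.43302742917386178	-0.64541636285449455	0.62922568617527974
P1	-0.22281840261944244	-0.6345556781910896	0.74006151820613297
Pz	7.1982932780599663e-17	-0.58778525229247314	0.80901699437494745
P2	0.22281840261944258	-0.6345556781910896	0.74006151820613286
P4	0.43302742917386178	-0.64541636285449444	0.62922568617527974
P6	0.61873127286755869	-0.61975269610850769	0.48278173913470096
P8	0.7694208842938135	-0.55901699437494745	0.30901699437494751
PO7	-0.55901699437494756	-0.76942088429381328	0.30901699437494745
PO3	-0.29429201708607272	-0.83096161983033456	0.47211756485896328
POz	9.907600726170916e-17	-0.80901699437494745	0.58778525229247314
PO4	0.29429201708607283	-0.83096161983033456	0.47211756485896328
PO8	0.55901699437494756	-0.76942088429381328	0.30901699437494745
O1	-0.29389262614623668	-0.90450849718747373	0.30901699437494751
Oz	1.1647083184890926e-16	-0.95105651629515364	0.30901699437494751
O2	0.29389262614623668	-0.90450849718747373	0.30901699437494751
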