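specimen_id	population	species_group	locus	haplotype	accession
Ben1	CLA BEN	CLA	COI	1	PP947873
Ben1	CLA BEN	CLA	16S	1	PP949387
Ben1	CLA BEN	CLA	ITS2	1	PP947951
Ben2	CLA BEN	CLA	COI	1	PP947874
Ben2	CLA BEN	CLA	16S	2	PP949388
Ben2	CLA BEN	CLA	ITS2	2	PP947952
Ben3	CLA BEN	CLA	COI	2	PP947875
Ben3	CLA BEN	CLA	16S	3	PP949389
Ben3	CLA BEN	CLA	ITS2	3	PP947953
Ben4	CLA BEN	CLA	COI	3	PP947876
Ben4	CLA BEN	CLA	16S	2	PP949390
Ben4	CLA BEN	CLA	ITS2	4	PP947954
Ben5	CLA BEN	CLA	COI	3	PP947877
Ben5	CLA BEN	CLA	16S	2	PP949391
Ben5	CLA BEN	CLA	ITS2	5	PP947955
Ben6	CLA BEN	CLA	COI	3	PP947878
Ben6	CLA BEN	CLA	16S	2	PP949392
Ben6	CLA BEN	CLA	ITS2	3	PP947956
Gar6	CLA GAR	CLA	COI	4	PP947879
Gar6	CLA GAR	CLA	16S	4	PP949393
Gar6	CLA GAR	CLA	ITS2	4	PP947957
Gar7	CLA GAR	CLA	COI	5	PP947880
Gar7	CLA GAR	CLA	16S	5	PP949394
Gar7	CLA GAR	CLA	ITS2	4	PP947958
Gar8	CLA GAR	CLA	COI	6	PP947881
Gar8	CLA GAR	CLA	16S	6	PP949395
Gar8	CLA GAR	CLA	ITS2	4	PP947959
Gar9	CLA GAR	CLA	COI	7	PP947882
Gar9	CLA GAR	CLA	16S	7	PP949396
Gar9	CLA GAR	CLA	ITS2	4	PP947960
Gar10	CLA GAR	CLA	COI	8	PP947883
Gar10	CLA GAR	CLA	16S	4	PP949397
Gar10	CLA GAR	CLA	ITS2	4	PP947961
Mol6	CLA MOL	CLA	COI	1	PP947884
Mol6	CLA MOL	CLA	16S	8	PP949398
Mol6	CLA MOL	CLA	ITS2	4	PP947962
Mol7	CLA MOL	CLA	COI	1	PP947885
Mol7	CLA MOL	CLA	16S	8	PP949399
Mol7	CLA MOL	CLA	ITS2	4	PP947963
Mol8	CLA MOL	CLA	COI	9	PP947886
Mol8	CLA MOL	CLA	16S	9	PP949400
Mol8	CLA MOL	CLA	ITS2	4	PP947964
Mol9	CLA MOL	CLA	COI	3	PP947887
Mol9	CLA MOL	CLA	16S	8	PP949401
Mol9	CLA MOL	CLA	ITS2	4	PP947965
Mol10	CLA MOL	CLA	COI	3	PP947888
Mol10	CLA MOL	CLA	16S	8	PP949402
Mol10	CLA MOL	CLA	ITS2	4	PP947966
Mol11	CLA MOL	CLA	COI	3	PP947889
Mol11	CLA MOL	CLA	16S	8	PP949403
Mol11	CLA MOL	CLA	ITS2	4	PP947967
ZMH86012	CLA GEO	CLA	COI		KX507199
ZMH86012	CLA GEO	CLA	16S		KX495388
ZMH86012	CLA GEO	CLA	ITS2		KX495441
Pnk1-1	PAR-K PNK1	PAR-K	COI	10	PP947890
Pnk1-1	PAR-K PNK1	PAR-K	16S	10	PP949404
Pnk1-1	PAR-K PNK1	PAR-K	ITS2	6	PP947968
Pnk1-2	PAR-K PNK1	PAR-K	COI	11	PP947891
Pnk1-2	PAR-K PNK1	PAR-K	16S	11	PP949405
Pnk1-2	PAR-K PNK1	PAR-K	ITS2	7	PP947969
Pnk1-3	PAR-K PNK1	PAR-K	COI	11	PP947892
Pnk1-3	PAR-K PNK1	PAR-K	16S	12	PP949406
Pnk1-3	PAR-K PNK1	PAR-K	ITS2	6	PP947970
Pnk1-4	PAR-K PNK1	PAR-K	COI	11	PP947893
Pnk1-4	PAR-K PNK1	PAR-K	16S	11	PP949407
Pnk1-4	PAR-K PNK1	PAR-K	ITS2	6	PP947971
Pnk1-5	PAR-K PNK1	PAR-K	COI	11	PP947894
Pnk1-5	PAR-K PNK1	PAR-K	16S	11	PP949408
Pnk1-5	PAR-K PNK1	PAR-K	ITS2	6	PP947972
Bim1-1	PAR-K BIM1	PAR-K	COI	12	PP947895
Bim1-1	PAR-K BIM1	PAR-K	16S	13	PP949409
Bim1-1	PAR-K BIM1	PAR-K	ITS2	8	PP947973
Bim1-2	PAR-K BIM1	PAR-K	COI	13	PP947896
Bim1-2	PAR-K BIM1	PAR-K	16S	14	PP949410
Bim1-2	PAR-K BIM1	PAR-K	ITS2	8	PP947974
Bim1-3	PAR-K BIM1	PAR-K	COI	14	PP947897
Bim1-3	PAR-K BIM1	PAR-K	16S	15	PP949411
Bim1-3	PAR-K BIM1	PAR-K	ITS2	8	PP947975
Bim1-4	PAR-K BIM1	PAR-K	COI	13	PP947898
Bim1-4	PAR-K BIM1	PAR-K	16S	16	PP949412
Bim1-4	PAR-K BIM1	PAR-K	ITS2	8	PP947976
Bim1-5	PAR-K BIM1	PAR-K	COI	13	PP947899
Bim1-5	PAR-K BIM1	PAR-K	16S	17	PP949413
Bim1-5	PAR-K BIM1	PAR-K	ITS2	8	PP947977
Pale1	PAR-K PAL	PAR-K	COI	15	PP947900
Pale1	PAR-K PAL	PAR-K	16S	18	PP949414
Pale1	PAR-K PAL	PAR-K	ITS2	8	PP947978
Pale2	PAR-K PAL	PAR-K	COI	16	PP947901
Pale2	PAR-K PAL	PAR-K	16S	19	PP949415
Pale2	PAR-K PAL	PAR-K	ITS2	8	PP947979
Pale3	PAR-K PAL	PAR-K	COI	17	PP947902
Pale3	PAR-K PAL	PAR-K	16S	20	PP949416
Pale3	PAR-K PAL	PAR-K	ITS2	8	PP947980
Pale4	PAR-K PAL	PAR-K	COI	13	PP947903
Pale4	PAR-K PAL	PAR-K	16S	21	PP949417
Pale4	PAR-K PAL	PAR-K	ITS2	8	PP947981
Pale5	PAR-K PAL	PAR-K	COI	17	PP947904
Pale5	PAR-K PAL	PAR-K	16S	20	PP949418
Pale5	PAR-K PAL	PAR-K	ITS2	8	PP947982
Pale6	PAR-K PAL	PAR-K	COI	17	PP947905
Pale6	PAR-K PAL	PAR-K	16S	20	PP949419
Pale6	PAR-K PAL	PAR-K	ITS2	8	PP947983
Cas-1	PAR-I CAS	PAR-I	COI		MG208959
Cas-1	PAR-I CAS	PAR-I	16S	22	PP949420
Cas-1	PAR-I CAS	PAR-I	ITS2	9	PP947984
15FG-1	PAR-I MOL	PAR-I	COI		MG208944
15FG-1	PAR-I MOL	PAR-I	16S	23	PP949421
15FG-1	PAR-I MOL	PAR-I	ITS2	10	PP947985
15FG-2	PAR-I MOL	PAR-I	COI		MG208947
15FG-2	PAR-I MOL	PAR-I	16S	24	PP949422
15FG-2	PAR-I MOL	PAR-I	ITS2	11	PP947986
Nie-2	PAR-I NIE	PAR-I	COI		MG208949
Nie-2	PAR-I NIE	PAR-I	16S	25	PP949423
Are-5	PAR-I ARE	PAR-I	COI		MG208950
Are-5	PAR-I ARE	PAR-I	16S	26	PP949424
Are-5	PAR-I ARE	PAR-I	ITS2	9	PP947987
Are-1	PAR-I ARE	PAR-I	COI		MG208956
Are-1	PAR-I ARE	PAR-I	16S	26	PP949425
Are-1	PAR-I ARE	PAR-I	ITS2	9	PP947988
Cur2	CUR	CAR	COI		ON332653
Cur2	CUR	CAR	16S		ON350961
Cur2	CUR	CAR	ITS2		ON332790
Cur4	CUR	CAR	COI		ON332655
Cur4	CUR	CAR	16S		ON350963
Cur4	CUR	CAR	ITS2	12	PP947989
Cur5	CUR	CAR	COI	18	PP947906
Cur5	CUR	CAR	16S		ON350964
Cur5	CUR	CAR	ITS2	13	PP947990
Wro10	WRO	CAR	COI	19	PP947907
Wro10	WRO	CAR	16S	27	PP949426
Wro10	WRO	CAR	ITS2	14	PP947991
Wro11	WRO	CAR	COI	19	PP947908
Wro11	WRO	CAR	16S	27	PP949427
Wro11	WRO	CAR	ITS2	14	PP947992
Wro12	WRO	CAR	COI	19	PP947909
Wro12	WRO	CAR	16S	27	PP949428
Wro12	WRO	CAR	ITS2	14	PP947993
Wro13	WRO	CAR	COI	20	PP947910
Wro13	WRO	CAR	16S	28	PP949429
Wro13	WRO	CAR	ITS2	14	PP947994
Wro14	WRO	CAR	COI	19	PP947911
Wro14	WRO	CAR	16S	27	PP949430
Wro14	WRO	CAR	ITS2	14	PP947995
Wro15	WRO	CAR	COI	20	PP947912
Wro15	WRO	CAR	16S	29	PP949431
Wro15	WRO	CAR	ITS2	14	PP947996
Wro20	WRO	CAR	COI	20	PP947913
Wro20	WRO	CAR	16S	27	PP949432
Wro20	WRO	CAR	ITS2	14	PP947997
Wro22	WRO	CAR	COI	21	PP947914
Wro22	WRO	CAR	16S	27	PP949433
Wro22	WRO	CAR	ITS2	14	PP947998
Wro23	WRO	CAR	COI	21	PP947915
Wro23	WRO	CAR	16S	27	PP949434
Wro23	WRO	CAR	ITS2	14	PP947999
Wro24	WRO	CAR	COI	19	PP947916
Wro24	WRO	CAR	16S	27	PP949435
Wro24	WRO	CAR	ITS2	14	PP948000
Wro16	WRO	CAR	COI	22	PP947917
Wro16	WRO	CAR	16S	30	PP949436
Wro16	WRO	CAR	ITS2	14	PP948001
Wro21	WRO	CAR	COI	22	PP947918
Wro21	WRO	CAR	16S	38	PP949437
Wro21	WRO	CAR	ITS2	14	PP948002
Que1	QUE	CAR	COI	23	PP947919
Que1	QUE	CAR	16S	31	PP949438
Que1	QUE	CAR	ITS2	1	PP948003
Que2	QUE	CAR	COI	24	PP947920
Que2	QUE	CAR	16S	32	PP949439
Que2	QUE	CAR	ITS2	1	PP948004
Que3	QUE	CAR	COI	23	PP947921
Que3	QUE	CAR	16S	31	PP949440
Que3	QUE	CAR	ITS2	1	PP948005
Que4	QUE	CAR	COI	24	PP947922
Que4	QUE	CAR	16S	31	PP949441
Que4	QUE	CAR	ITS2	1	PP948006
Que5	QUE	CAR	COI	25	PP947923
Que5	QUE	CAR	16S	33	PP949442
Que5	QUE	CAR	ITS2	1	PP948007
ZMH51710	ANF	CAR	COI		KX507189
ZMH51710	ANF	CAR	16S		KX495378
ZMH51710	ANF	CAR	ITS2		KX495431
SP166	SPA	CAR	COI		KX507235
SP166	SPA	CAR	16S		KX495429
SP166	SPA	CAR	ITS2		KX495479
4FG-1	CAN-1	CAN	COI		MG208905
4FG-1	CAN-1	CAN	16S		OR918428
4FG-1	CAN-1	CAN	ITS2		OR917402
4FG-2	CAN-1	CAN	COI		MG208910
4FG-2	CAN-1	CAN	16S		OR918429
4FG-2	CAN-1	CAN	ITS2		OR917403
12FG-1	CAN-2	CAN	COI		MG208925
12FG-1	CAN-2	CAN	16S		OR918435
12FG-1	CAN-2	CAN	ITS2		OR917406
12FG-2	CAN-2	CAN	COI		MG208928
12FG-2	CAN-2	CAN	16S		OR918436
12FG-2	CAN-2	CAN	ITS2		OR917407
Dud2	CAN-3	CAN	COI		MG208938
Dud2	CAN-3	CAN	16S		OR918437
Dud2	CAN-3	CAN	ITS2		OR917408
3FG-1	CAN-4	CAN	COI		MG208939
3FG-1	CAN-4	CAN	16S		OR918438
3FG-1	CAN-4	CAN	ITS2		OR917409
3FG-2	CAN-4	CAN	COI		MG208940
3FG-2	CAN-4	CAN	16S		OR918439
3FG-2	CAN-4	CAN	ITS2		OR917410
Pia2	CAN-5	CAN	COI		MK066938
Pia2	CAN-5	CAN	16S	34	PP949443
Pia2	CAN-5	CAN	ITS2	15	PP948008
5FG-1	CAN-6	CAN	COI		MK066944
5FG-1	CAN-6	CAN	16S	35	PP949444
5FG-1	CAN-6	CAN	ITS2	16	PP948009
5FG-2	CAN-6	CAN	COI		MK066943
5FG-2	CAN-6	CAN	16S	36	PP949445
5FG-2	CAN-6	CAN	ITS2	16	PP948010
Fio3	FIO	PAN	COI		MT380015
Fio3	FIO	PAN	16S	37	PP949446
Fio3	FIO	PAN	ITS2	17	PP948011
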