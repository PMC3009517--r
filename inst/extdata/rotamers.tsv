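restype	rotamer	atom	x	y	z
A	1	CB	-0.5358	-0.7718	1.2075
R	1	CB	-0.5358	-0.7718	1.2075
R	1	CG	-0.1034	-0.2033	2.5492
R	1	CD	-0.6698	-1.0163	3.7018
R	1	NE	-0.2636	-0.4830	4.9989
R	1	CZ	-0.6214	-1.0069	6.1678
R	1	NH1	-1.3983	-2.0858	6.2031
R	1	NH2	-0.2022	-0.4519	7.3015
R	2	CB	-0.5358	-0.7718	1.2075
R	2	CG	-2.0528	-0.8232	1.2879
R	2	CD	-2.5149	-1.6030	2.5081
R	2	NE	-3.9708	-1.6620	2.6003
R	2	CZ	-4.6338	-2.2829	3.5718
R	2	NH1	-3.9668	-2.9026	4.5413
R	2	NH2	-5.9638	-2.2842	3.5737
R	3	CB	-0.5358	-0.7718	1.2075
R	3	CG	-0.1034	-2.2282	1.2550
R	3	CD	-0.6698	-2.9329	2.4768
R	3	NE	-0.2636	-4.3339	2.5376
R	3	CZ	-0.6214	-5.1748	3.5039
R	3	NH1	-1.3983	-4.7538	4.4979
R	3	NH2	-0.2022	-6.4367	3.4763
N	1	CB	-0.5358	-0.7718	1.2075
N	1	CG	-0.0832	-0.1748	2.5301
N	1	OD1	0.6361	0.8226	2.5575
N	1	ND2	-0.5066	-0.7882	3.6316
N	2	CB	-0.5358	-0.7718	1.2075
N	2	CG	-2.0548	-0.8018	1.2545
N	2	OD1	-2.7229	-0.2456	0.3843
N	2	ND2	-2.6021	-1.4546	2.2758
N	3	CB	-0.5358	-0.7718	1.2075
N	3	CG	-0.0832	-2.2228	1.2211
N	3	OD1	0.6361	-2.6665	0.3275
N	3	ND2	-0.5066	-2.9648	2.2404
D	1	CB	-0.5358	-0.7718	1.2075
D	1	CG	-0.0832	-0.1748	2.5301
D	1	OD1	0.6473	0.8393	2.5056
D	1	OD2	-0.4595	-0.7219	3.5891
D	2	CB	-0.5358	-0.7718	1.2075
D	2	CG	-2.0548	-0.8018	1.2545
D	2	OD1	-2.6892	-0.2218	0.3470
D	2	OD2	-2.6086	-1.4053	2.1987
D	3	CB	-0.5358	-0.7718	1.2075
D	3	CG	-0.0832	-2.2228	1.2211
D	3	OD1	0.6473	-2.6264	0.2905
D	3	OD2	-0.4595	-2.9542	2.1623
C	1	CB	-0.5358	-0.7718	1.2075
C	1	SG	-0.0192	-0.0925	2.8037
C	2	CB	-0.5358	-0.7718	1.2075
C	2	SG	-2.3424	-0.8313	1.3006
C	3	CB	-0.5358	-0.7718	1.2075
C	3	SG	-0.0192	-2.5057	1.2613
Q	1	CB	-0.5358	-0.7718	1.2075
Q	1	CG	-0.1034	-0.2033	2.5492
Q	1	CD	-0.6541	-0.9950	3.7240
Q	1	OE1	-1.3673	-1.9802	3.5406
Q	1	NE2	-0.3216	-0.5621	4.9368
Q	2	CB	-0.5358	-0.7718	1.2075
Q	2	CG	-2.0528	-0.8232	1.2879
Q	2	CD	-2.5477	-1.5972	2.4989
Q	2	OE1	-1.7538	-2.1031	3.2905
Q	2	NE2	-3.8666	-1.6894	2.6433
Q	3	CB	-0.5358	-0.7718	1.2075
Q	3	CG	-0.1034	-2.2282	1.2550
Q	3	CD	-0.6541	-2.9619	2.4669
Q	3	OE1	-1.3673	-2.3817	3.2840
Q	3	NE2	-0.3216	-4.2444	2.5833
E	1	CB	-0.5358	-0.7718	1.2075
E	1	CG	-0.1034	-0.2033	2.5492
E	1	CD	-0.6541	-0.9950	3.7240
E	1	OE1	-1.3743	-1.9886	3.4860
E	1	OE2	-0.3648	-0.6208	4.8811
E	2	CB	-0.5358	-0.7718	1.2075
E	2	CG	-2.0528	-0.8232	1.2879
E	2	CD	-2.5477	-1.5972	2.4989
E	2	OE1	-1.7016	-2.0927	3.2742
E	2	OE2	-3.7809	-1.7071	2.6709
E	3	CB	-0.5358	-0.7718	1.2075
E	3	CG	-0.1034	-2.2282	1.2550
E	3	CD	-0.6541	-2.9619	2.4669
E	3	OE1	-1.3743	-2.3286	3.2687
E	3	OE2	-0.3648	-4.1691	2.6131
H	1	CB	-0.5358	-0.7718	1.2075
H	1	CG	-0.1050	-0.2051	2.5279
H	1	ND1	1.0511	-0.6023	3.1682
H	1	CD2	-0.6796	0.7318	3.3289
H	1	CE1	1.1697	0.0627	4.3022
H	1	NE2	0.1336	0.8727	4.4154
H	2	CB	-0.5358	-0.7718	1.2075
H	2	CG	-2.0333	-0.8183	1.2803
H	2	ND1	-2.7776	0.1371	1.9419
H	2	CD2	-2.9259	-1.7095	0.7717
H	2	CE1	-4.0590	-0.1624	1.8382
H	2	NE2	-4.1670	-1.2742	1.1349
H	3	CB	-0.5358	-0.7718	1.2075
H	3	CG	-0.1050	-2.2080	1.2477
H	3	ND1	-0.8329	-3.2215	0.6581
H	3	CD2	0.9830	-2.7997	1.8094
H	3	CE1	-0.2144	-4.3710	0.8542
H	3	NE2	0.8838	-4.1352	1.5475
I	1	CB	-0.5358	-0.7718	1.2075
I	1	CG1	-0.0523	-0.1315	2.5103
I	1	CG2	-2.0558	-0.7718	1.2075
I	1	CD1	-0.5530	-0.8554	3.7495
I	2	CB	-0.5358	-0.7718	1.2075
I	2	CG1	-2.0658	-0.7718	1.2075
I	2	CG2	-0.0554	-2.2135	1.1737
I	2	CD1	-2.6597	-1.5253	2.3865
I	3	CB	-0.5358	-0.7718	1.2075
I	3	CG1	-0.0523	-2.2230	1.1735
I	3	CG2	-0.0554	-0.1357	2.5017
I	3	CD1	-0.5530	-3.0436	2.3508
L	1	CB	-0.5358	-0.7718	1.2075
L	1	CG	-0.1267	-0.2363	2.5811
L	1	CD1	-0.7248	-1.0921	3.6858
L	1	CD2	1.3861	-0.2499	2.7287
L	2	CB	-0.5358	-0.7718	1.2075
L	2	CG	-2.0588	-0.8508	1.3311
L	2	CD1	-2.4522	-1.6415	2.5682
L	2	CD2	-2.6569	0.5423	1.4411
L	3	CB	-0.5358	-0.7718	1.2075
L	3	CG	-0.1267	-2.2433	1.2984
L	3	CD1	-0.7248	-2.8864	2.5390
L	3	CD2	-0.6143	-3.0077	0.0784
K	1	CB	-0.5358	-0.7718	1.2075
K	1	CG	-0.1034	-0.2033	2.5492
K	1	CD	-0.6698	-1.0163	3.7018
K	1	CE	-0.2374	-0.4477	5.0435
K	1	NZ	-0.7856	-1.2351	6.1835
K	2	CB	-0.5358	-0.7718	1.2075
K	2	CG	-2.0528	-0.8232	1.2879
K	2	CD	-2.5149	-1.6030	2.5081
K	2	CE	-4.0319	-1.6544	2.5885
K	2	NZ	-4.4998	-2.4163	3.7805
K	3	CB	-0.5358	-0.7718	1.2075
K	3	CG	-0.1034	-2.2282	1.2550
K	3	CD	-0.6698	-2.9329	2.4768
K	3	CE	-0.2374	-4.3893	2.5243
K	3	NZ	-0.7856	-5.0932	3.7176
M	1	CB	-0.5358	-0.7718	1.2075
M	1	CG	-0.1020	-0.2013	2.5480
M	1	SD	-0.7513	-1.1351	3.9432
M	1	CE	-0.0644	-0.2142	5.3158
M	2	CB	-0.5358	-0.7718	1.2075
M	2	CG	-2.0530	-0.8218	1.2857
M	2	SD	-2.6449	-1.7372	2.7180
M	2	CE	-4.4162	-1.5981	2.5003
M	3	CB	-0.5358	-0.7718	1.2075
M	3	CG	-0.1020	-2.2279	1.2527
M	3	SD	-0.7513	-3.1020	2.6860
M	3	CE	-0.0644	-4.7345	2.4267
F	1	CB	-0.5358	-0.7718	1.2075
F	1	CG	-0.1050	-0.2051	2.5279
F	1	CD1	1.0683	-0.6357	3.1361
F	1	CD2	-0.8708	0.7618	3.1689
F	1	CE1	1.4537	-0.1007	4.3598
F	1	CE2	-0.4578	1.2770	4.3921
F	1	CZ	0.6657	0.8650	4.9752
F	2	CB	-0.5358	-0.7718	1.2075
F	2	CG	-2.0333	-0.8183	1.2803
F	2	CD1	-2.7418	0.1668	1.9584
F	2	CD2	-2.7418	-1.8474	0.6710
F	2	CE1	-4.1294	0.1094	2.0166
F	2	CE2	-4.1294	-1.8761	0.7476
F	2	CZ	-4.8085	-0.9331	1.3968
F	3	CB	-0.5358	-0.7718	1.2075
F	3	CG	-0.1050	-2.2080	1.2477
F	3	CD1	-0.8708	-3.1959	0.6394
F	3	CD2	1.0683	-2.5792	1.8939
F	3	CE1	-0.4578	-4.5223	0.6855
F	3	CE2	1.4537	-3.9144	1.9222
F	3	CZ	0.7208	-4.8609	1.3399
P	1	CB	-0.5358	-0.7718	1.2075
P	1	CG	0.5037	-0.5879	2.2590
P	1	CD	1.8136	-0.5668	1.5285
S	1	CB	-0.5358	-0.7718	1.2075
S	1	OG	-0.0871	-0.1775	2.4166
S	2	CB	-0.5358	-0.7718	1.2075
S	2	OG	-1.9558	-0.7718	1.2075
S	3	CB	-0.5358	-0.7718	1.2075
S	3	OG	-0.0871	-2.1186	1.1759
T	1	CB	-0.5358	-0.7718	1.2075
T	1	OG1	-0.0717	-0.1561	2.4118
T	1	CG2	-0.0554	-2.2135	1.1737
T	2	CB	-0.5358	-0.7718	1.2075
T	2	OG1	-1.9656	-0.7584	1.1865
T	2	CG2	-0.0554	-0.1357	2.5017
T	3	CB	-0.5358	-0.7718	1.2075
T	3	OG1	-0.0717	-2.1233	1.1545
T	3	CG2	-2.0558	-0.7718	1.2075
W	1	CB	-0.5358	-0.7718	1.2075
W	1	CG	-0.1024	-0.2013	2.5254
W	1	CD1	1.0240	-0.5290	3.2330
W	1	CD2	-0.7837	0.7939	3.2937
W	1	NE1	1.0843	0.2055	4.3997
W	1	CE2	-0.0162	1.0225	4.4542
W	1	CE3	-1.9698	1.5156	3.1139
W	1	CZ2	-0.3966	1.9460	5.4352
W	1	CZ3	-2.3455	2.4319	4.0892
W	1	CH2	-1.5614	2.6386	5.2344
W	2	CB	-0.5358	-0.7718	1.2075
W	2	CG	-2.0336	-0.8155	1.2759
W	2	CD1	-2.8550	0.0837	1.9034
W	2	CD2	-2.8890	-1.8052	0.6983
W	2	NE1	-4.1749	-0.2890	1.7500
W	2	CE2	-4.2153	-1.4454	1.0135
W	2	CE3	-2.6631	-2.9628	-0.0561
W	2	CZ2	-5.3169	-2.2038	0.5996
W	2	CZ3	-3.7583	-3.7142	-0.4660
W	2	CH2	-5.0676	-3.3315	-0.1372
W	3	CB	-0.5358	-0.7718	1.2075
W	3	CG	-0.1024	-2.2074	1.2432
W	3	CD1	-0.7534	-3.2772	0.6878
W	3	CD2	1.0740	-2.7318	1.8645
W	3	NE1	-0.0498	-4.4399	0.9274
W	3	CE2	1.0741	-4.1251	1.6479
W	3	CE3	2.1293	-2.1589	2.5842
W	3	CZ2	2.0921	-4.9585	2.1265
W	3	CZ3	3.1389	-2.9883	3.0585
W	3	CH2	3.1127	-4.3721	2.8275
Y	1	CB	-0.5358	-0.7718	1.2075
Y	1	CG	-0.1022	-0.2013	2.5367
Y	1	CD1	1.0703	-0.6289	3.1486
Y	1	CD2	-0.8647	0.7657	3.1814
Y	1	CE1	1.4518	-0.0911	4.3723
Y	1	CE2	-0.4478	1.2780	4.4044
Y	1	CZ	0.6607	0.8744	4.9840
Y	1	OH	1.0394	1.4084	6.1988
Y	2	CB	-0.5358	-0.7718	1.2075
Y	2	CG	-2.0433	-0.8186	1.2808
Y	2	CD1	-2.7560	0.1642	1.9577
Y	2	CD2	-2.7560	-1.8457	0.6731
Y	2	CE1	-4.1435	0.1028	2.0134
Y	2	CE2	-4.1435	-1.8704	0.7522
Y	2	CZ	-4.8184	-0.9416	1.3921
Y	2	OH	-6.1959	-1.0026	1.4473
Y	3	CB	-0.5358	-0.7718	1.2075
Y	3	CG	-0.1022	-2.2176	1.2479
Y	3	CD1	-0.8647	-3.2088	0.6411
Y	3	CD2	1.0703	-2.5934	1.8930
Y	3	CE1	-0.4478	-4.5339	0.6897
Y	3	CE2	1.4518	-3.9298	1.9187
Y	3	CZ	0.7315	-4.8679	1.3452
Y	3	OH	1.1454	-6.1835	1.3935
V	1	CB	-0.5358	-0.7718	1.2075
V	1	CG1	-0.0554	-0.1357	2.5017
V	1	CG2	-0.0554	-2.2135	1.1737
V	2	CB	-0.5358	-0.7718	1.2075
V	2	CG1	-2.0558	-0.7718	1.2075
V	2	CG2	-0.0554	-0.1357	2.5017
V	3	CB	-0.5358	-0.7718	1.2075
V	3	CG1	-0.0554	-2.2135	1.1737
V	3	CG2	-2.0558	-0.7718	1.2075
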