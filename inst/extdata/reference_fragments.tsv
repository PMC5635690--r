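molecule	calc_mz	obs_mz
1	137.0239	137.0231
1	194.0817	194.0809
1Tc	137.0239	137.0230
1Tc	194.0817	194.0811
1Tc	277.1175	277.1188
1Tc	294.1443	294.1457
2	72.0813	72.0813
2	129.1392	129.1388
2	194.0817	194.0810
2	265.1552	265.1542
2Tc	194.0817	194.0812
2Tc	265.1552	265.1540
2Tc	308.1610	308.1595
2Tc	365.2178	365.2173
2So	137.0239	137.0237
2So	209.0926	209.0924
2So	224.0559	224.0555
2To	137.0239	137.0232
2To	194.0817	194.0809
2To	210.0766	210.0758
2To	265.1552	265.1542
2To	282.1807	282.1809
2To	383.2283	383.2294
4	86.0970	86.0970
4	103.1229	103.1235
4	137.0239	137.0232
4	222.1130	222.1132
5	72.0813	72.0815
5	89.1068	89.1080
5	137.0239	137.0234
5	208.0974	208.0968
5Tc	137.0239	137.0229
5Tc	192.0661	192.0661
5Tc	208.0974	208.0964
5Tc	225.1228	225.1237
5Tc	308.1599	308.1617
5To	137.0239	137.0230
5To	208.0974	208.0964
5To	225.1228	225.1237
5To	238.0715	238.0717
5To	210.0766	210.0755
6	137.0239	137.0232
6	194.0817	194.0810
6	251.1396	251.1381
6	443.1925	443.1907
6Tc	137.0239	137.0232
6Tc	194.0817	194.0810
6Tc	277.1188	277.1188
6Tc	351.2021	351.2016
6Tc	443.1925	443.1907
6To	137.0239	137.0232
6To	194.0817	194.0810
6To	210.0766	210.0758
6To	369.2127	369.2130
7	120.0813	120.0811
7	137.0239	137.0232
7	256.0974	256.0964
9	91.0548	91.0545
9	180.0661	180.0651
9Tc	91.0548	91.0546
9Tc	180.0661	180.0652
9Tc	287.1385	287.1381
9Sc	91.0548	91.0548
9Sc	287.1385	287.1385
9To	91.0548	91.0548
9To	345.1439	345.1460
9To	389.1934	389.1956
10	106.0657	106.0656
10	137.0239	137.0237
10	154.0493	154.0497
11	120.0813	120.0813
11	137.0239	137.0234
11	256.0974	256.0963
12	108.0449	108.0446
12	137.0239	137.0232
12	201.1017	201.1024
21	128.1439	128.1435
21	137.0239	137.0231
21	145.1694	145.1699
21	264.1600	264.1595
Ent	137.0239	137.02134
Ent	206.0459	206.0452
Ent	224.0553	224.0554
Ent	447.1034	447.1029
Ent trimer	137.0239	137.0230
Ent trimer	224.0559	224.0555
Ent trimer	447.1040	447.1018
Ent dimer	137.02139	137.0231
Ent dimer	196.0610	196.0609
Ent dimer	224.0559	224.0557
Ent monomer	106.0493	106.0503
Ent monomer	137.0239	137.0234
Thr-Ent dimer	137.0239	137.02131
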