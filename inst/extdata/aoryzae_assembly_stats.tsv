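assembly	contig	scaffold	ratio_printed	n50_kb
lib2.8.nofilter.k31	5332	1184	4.50	1677
lib2.8.nodot.k31	5265	1147	4.59	1361
lib2.8.qv10.k31	7763	2751	2.82	983
lib2.8.qv10.k25	9448	4182	2.26	1379
lib2.8.qv10.k27	8960	3790	2.36	1344
lib2.8.qv10.k29	8321	3220	2.58	1538
lib2.8.qv10.k33	7179	2260	3.18	1230
lib2.8.qv10.k35	6702	1774	3.78	1364
lib1.9.nodot.k31	7153	2456	2.91	913
lib1.9.qv10.k31	8254	3050	2.71	876
lib1.9.qv10.k25	10278	4468	2.30	775
lib1.9.qv10.k27	9704	4109	2.36	843
lib1.9.qv10.k29	9066	3601	2.52	876
lib1.9.qv10.k33	7545	2465	3.06	848
lib1.9.qv10.k35	6893	1828	3.77	820
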