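Precentral_L	Precentral_R	Rolandic_Oper_R	Supp_Motor_Area_L
1057.18	1030.46	1008.56	961.13
970.08	982.52	1000.11	1039.25
982.64	992.86	1000.73	1017.21
989.69	967.21	990.16	995.56
975.73	990.22	980.18	1018.23
976.32	989.96	992.21	1038.33
1018.7	1033.76	991.35	1012.66
997.08	1014.78	992.38	1000.83
1003.82	1002.51	955.35	963.31
1054.75	1023.28	1014.68	1025.48
1008.92	993.43	1040.89	985.17
1067.92	999.81	983.86	1020.31
1057.04	1009.18	1015.47	1021.65
1008.1	1042.68	1005.91	1009.21
1047.4	1018.09	1021.16	1028.37
1011.69	1012.03	985.66	981.07
977.65	960.8	1027.95	1011.13
992.32	1007.96	961.5	1022.9
999.88	1004.15	989.05	1006.74
1024.7	977.5	996.23	1025.19
1020.99	1001.91	1012.98	963.46
1017.63	1003.98	1014.69	978.13
1032.65	1013.59	998.02	1004.13
965.3	1017.62	970.64	1005.18
1031.82	1007.97	1007.72	1012.06
1004.6	1027.73	959.9	998.21
1018.81	1019.23	1024.78	977.78
1014.79	1028.84	1025.58	1012.15
975.42	1031.52	1021	1008.51
993.1	1017.52	1003	972.55
978.23	1010.82	989.34	991.11
1017.97	976.93	1011.47	1027.43
1002.77	984.61	1016.13	977.33
998.04	978.33	1015.29	994.81
989.49	959.01	977.77	1016.97
985.95	966.85	1038.6	980.06
1024.94	977.77	968.96	960.21
972.37	986.06	1027.59	1029.51
996.44	998.44	1024.57	1030.56
1007.87	1060.57	1007.61	999.73
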