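# Synthetic compilation of pure lipid absorption, cm^-1.
# Generated by data-raw/make_spectra.R.
wavelength_nm,mu_a_cm1
650,0.005
652,0.00508
654,0.00515
656,0.00522
658,0.00529
660,0.00535
662,0.00541
664,0.00548
666,0.00554
668,0.0056
670,0.00566
672,0.00572
674,0.00578
676,0.00585
678,0.00591
680,0.00598
682,0.00606
684,0.00614
686,0.00622
688,0.00631
690,0.00641
692,0.00651
694,0.00662
696,0.00674
698,0.00686
700,0.007
702,0.00715
704,0.00733
706,0.00752
708,0.00774
710,0.00797
712,0.00821
714,0.00846
716,0.00873
718,0.00899
720,0.00926
722,0.00954
724,0.0098
726,0.01007
728,0.01033
730,0.01058
732,0.01081
734,0.01104
736,0.01124
738,0.01143
740,0.01159
742,0.01173
744,0.01185
746,0.01193
748,0.01198
750,0.012
752,0.01198
754,0.01191
756,0.0118
758,0.01166
760,0.01148
762,0.01127
764,0.01104
766,0.01079
768,0.01052
770,0.01024
772,0.00995
774,0.00965
776,0.00935
778,0.00905
780,0.00876
782,0.00848
784,0.00821
786,0.00796
788,0.00773
790,0.00752
792,0.00734
794,0.0072
796,0.00709
798,0.00702
800,0.007
802,0.007
804,0.007
806,0.00701
808,0.00702
810,0.00704
812,0.00707
814,0.00711
816,0.00716
818,0.00723
820,0.00732
822,0.00743
824,0.00755
826,0.0077
828,0.00788
830,0.00808
832,0.00831
834,0.00857
836,0.00887
838,0.00919
840,0.00956
842,0.00996
844,0.01041
846,0.01089
848,0.01142
850,0.012
852,0.01257
854,0.01307
856,0.01354
858,0.01397
860,0.01438
862,0.01479
864,0.01522
866,0.01566
868,0.01614
870,0.01667
872,0.01727
874,0.01794
876,0.01871
878,0.01958
880,0.02057
882,0.02169
884,0.02296
886,0.02439
888,0.02599
890,0.02778
892,0.02976
894,0.03197
896,0.0344
898,0.03707
900,0.04
902,0.04354
904,0.04795
906,0.05308
908,0.05876
910,0.06486
912,0.07121
914,0.07767
916,0.08409
918,0.09031
920,0.09618
922,0.10155
924,0.10627
926,0.11018
928,0.11315
930,0.115
932,0.11552
934,0.11475
936,0.11292
938,0.11026
940,0.107
942,0.10338
944,0.09964
946,0.09601
948,0.09272
950,0.09
952,0.0876
954,0.08511
956,0.08254
958,0.07992
960,0.07724
962,0.07453
964,0.0718
966,0.06906
968,0.06633
970,0.06362
972,0.06095
974,0.05832
976,0.05576
978,0.05327
980,0.05088
982,0.04859
984,0.04642
986,0.04438
988,0.04249
990,0.04076
992,0.0392
994,0.03784
996,0.03667
998,0.03572
1000,0.035
1002,0.03459
1004,0.03454
1006,0.0348
1008,0.03536
1010,0.03616
1012,0.03719
1014,0.0384
1016,0.03975
1018,0.04122
1020,0.04277
1022,0.04436
1024,0.04597
1026,0.04755
1028,0.04907
1030,0.05049
1032,0.05179
1034,0.05292
1036,0.05386
1038,0.05456
1040,0.055
1042,0.05518
1044,0.05517
1046,0.05498
1048,0.05465
1050,0.05421
1052,0.05367
1054,0.05306
1056,0.05242
1058,0.05177
1060,0.05113
1062,0.05053
1064,0.05
1066,0.04945
1068,0.04879
1070,0.04803
1072,0.0472
1074,0.04632
1076,0.04541
1078,0.0445
1080,0.0436
1082,0.04273
1084,0.04192
1086,0.04119
1088,0.04055
1090,0.04004
1092,0.03966
1094,0.03945
1096,0.03942
1098,0.0396
1100,0.04
1102,0.04047
1104,0.04085
1106,0.04116
1108,0.04142
1110,0.04167
1112,0.04193
1114,0.04221
1116,0.04255
1118,0.04296
1120,0.04348
1122,0.04412
1124,0.04492
1126,0.04589
1128,0.04706
1130,0.04845
1132,0.05009
1134,0.05201
1136,0.05422
1138,0.05674
1140,0.05962
1142,0.06286
1144,0.0665
1146,0.07055
1148,0.07504
1150,0.08
1152,0.0855
1154,0.09156
1156,0.09816
1158,0.10525
1160,0.1128
1162,0.12076
1164,0.1291
1166,0.13778
1168,0.14676
1170,0.156
1172,0.16547
1174,0.17512
1176,0.18492
1178,0.19482
1180,0.2048
1182,0.21481
1184,0.22481
1186,0.23477
1188,0.24465
1190,0.2544
1192,0.26399
1194,0.27339
1196,0.28255
1198,0.29143
1200,0.3
1202,0.30938
1204,0.31965
1206,0.32923
1208,0.33654
1210,0.34
1212,0.33963
1214,0.33682
1216,0.33202
1218,0.32567
1220,0.31821
1222,0.3101
1224,0.30178
1226,0.29369
1228,0.28628
1230,0.28
1232,0.27433
1234,0.26847
1236,0.26244
1238,0.25626
1240,0.24995
1242,0.24353
1244,0.23702
1246,0.23045
1248,0.22383
1250,0.21717
1252,0.21051
1254,0.20386
1256,0.19724
1258,0.19067
1260,0.18418
1262,0.17777
1264,0.17147
1266,0.16531
1268,0.1593
1270,0.15346
1272,0.14781
1274,0.14237
1276,0.13716
1278,0.13221
1280,0.12752
1282,0.12313
1284,0.11905
1286,0.1153
1288,0.1119
1290,0.10887
1292,0.10623
1294,0.10401
1296,0.10221
1298,0.10087
1300,0.1
1302,0.09943
1304,0.09896
1306,0.0986
1308,0.09835
1310,0.09822
1312,0.09819
1314,0.09828
1316,0.09848
1318,0.09879
1320,0.09922
1322,0.09976
1324,0.10042
1326,0.1012
1328,0.1021
1330,0.10311
1332,0.10425
1334,0.1055
1336,0.10688
1338,0.10838
1340,0.11001
1342,0.11175
1344,0.11362
1346,0.11562
1348,0.11775
1350,0.12
1352,0.12316
1354,0.12794
1356,0.13427
1358,0.14207
1360,0.15125
1362,0.16173
1364,0.17344
1366,0.18628
1368,0.20018
1370,0.21506
1372,0.23083
1374,0.24742
1376,0.26473
1378,0.2827
1380,0.30124
1382,0.32026
1384,0.3397
1386,0.35945
1388,0.37945
1390,0.39961
1392,0.41986
1394,0.4401
1396,0.46026
1398,0.48025
1400,0.5
1402,0.52056
1404,0.54291
1406,0.56685
1408,0.59218
1410,0.61872
1412,0.64626
1414,0.67461
1416,0.70358
1418,0.73296
1420,0.76256
1422,0.79219
1424,0.82165
1426,0.85074
1428,0.87927
1430,0.90704
1432,0.93386
1434,0.95953
1436,0.98385
1438,1.00663
1440,1.02768
1442,1.04679
1444,1.06378
1446,1.07844
1448,1.09058
1450,1.1
1452,1.10671
1454,1.11094
1456,1.11285
1458,1.11262
1460,1.1104
1462,1.10636
1464,1.10065
1466,1.09345
1468,1.08491
1470,1.0752
1472,1.06448
1474,1.05292
1476,1.04068
1478,1.02792
1480,1.0148
1482,1.00149
1484,0.98815
1486,0.97495
1488,0.96204
1490,0.9496
1492,0.93778
1494,0.92675
1496,0.91666
1498,0.90769
1500,0.9
1502,0.89251
1504,0.88408
1506,0.87478
1508,0.86467
1510,0.8538
1512,0.84225
1514,0.83007
1516,0.81732
1518,0.80408
1520,0.7904
1522,0.77634
1524,0.76197
1526,0.74735
1528,0.73254
1530,0.7176
1532,0.7026
1534,0.6876
1536,0.67265
1538,0.65783
1540,0.6432
1542,0.62881
1544,0.61474
1546,0.60104
1548,0.58777
1550,0.575
1552,0.56279
1554,0.5512
1556,0.5403
1558,0.53015
1560,0.5208
1562,0.51233
1564,0.50479
1566,0.49824
1568,0.49276
1570,0.4884
1572,0.48522
1574,0.48329
1576,0.48267
1578,0.48342
1580,0.4856
1582,0.48928
1584,0.49452
1586,0.50137
1588,0.50991
1590,0.5202
1592,0.53229
1594,0.54626
1596,0.56216
1598,0.58005
1600,0.6
1602,0.62156
1604,0.64424
1606,0.66803
1608,0.69293
1610,0.71895
1612,0.74607
1614,0.7743
1616,0.80364
1618,0.83407
1620,0.8656
1622,0.89823
1624,0.93195
1626,0.96676
1628,1.00266
1630,1.03965
1632,1.07772
1634,1.11687
1636,1.15711
1638,1.19842
1640,1.2408
1642,1.28426
1644,1.32878
1646,1.37437
1648,1.42103
1650,1.46875
1652,1.51753
1654,1.56737
1656,1.61826
1658,1.6702
1660,1.7232
1662,1.77724
1664,1.83233
1666,1.88847
1668,1.94564
1670,2.00385
1672,2.0631
1674,2.12338
1676,2.18469
1678,2.24703
1680,2.3104
1682,2.37479
1684,2.4402
1686,2.50664
1688,2.57409
1690,2.64255
1692,2.71203
1694,2.78251
1696,2.854
1698,2.9265
1700,3
1702,3.08704
1704,3.19552
1706,3.31848
1708,3.44896
1710,3.58
1712,3.70464
1714,3.81592
1716,3.90688
1718,3.97056
1720,4
1722,3.99815
1724,3.97428
1726,3.93088
1728,3.87047
1730,3.79556
1732,3.70864
1734,3.61223
1736,3.50884
1738,3.40096
1740,3.29111
1742,3.1818
1744,3.07552
1746,2.97479
1748,2.88212
1750,2.8
1752,2.72431
1754,2.64923
1756,2.57471
1758,2.50071
1760,2.4272
1762,2.35414
1764,2.28148
1766,2.2092
1768,2.13725
1770,2.0656
1772,1.9942
1774,1.92302
1776,1.85202
1778,1.78116
1780,1.7104
1782,1.63971
1784,1.56904
1786,1.49836
1788,1.42762
1790,1.3568
1792,1.28585
1794,1.21473
1796,1.14341
1798,1.07185
1800,1
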