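# Synthetic compilation of pure water absorption, cm^-1.
# Generated by data-raw/make_spectra.R.
wavelength_nm,mu_a_cm1
650,0.0032
652,0.00327
654,0.00334
656,0.00339
658,0.00344
660,0.00348
662,0.00352
664,0.00356
666,0.0036
668,0.00364
670,0.00369
672,0.00374
674,0.0038
676,0.00386
678,0.00394
680,0.00403
682,0.00413
684,0.00425
686,0.00439
688,0.00455
690,0.00473
692,0.00493
694,0.00516
696,0.00541
698,0.00569
700,0.006
702,0.00638
704,0.00687
706,0.00746
708,0.00814
710,0.00889
712,0.00971
714,0.0106
716,0.01153
718,0.01251
720,0.01352
722,0.01455
724,0.0156
726,0.01665
728,0.01769
730,0.01872
732,0.01973
734,0.0207
736,0.02164
738,0.02252
740,0.02334
742,0.02409
744,0.02476
746,0.02534
748,0.02582
750,0.0262
752,0.02646
754,0.02662
756,0.02667
758,0.02663
760,0.02652
762,0.02633
764,0.02608
766,0.02578
768,0.02544
770,0.02507
772,0.02467
774,0.02426
776,0.02384
778,0.02343
780,0.02304
782,0.02267
784,0.02233
786,0.02204
788,0.0218
790,0.02162
792,0.02151
794,0.02149
796,0.02155
798,0.02172
800,0.022
802,0.02239
804,0.02289
806,0.02349
808,0.02418
810,0.02494
812,0.02578
814,0.02668
816,0.02763
818,0.02862
820,0.02965
822,0.0307
824,0.03177
826,0.03285
828,0.03392
830,0.03499
832,0.03603
834,0.03704
836,0.03802
838,0.03895
840,0.03982
842,0.04062
844,0.04135
846,0.042
848,0.04255
850,0.043
852,0.04337
854,0.04369
856,0.04397
858,0.04424
860,0.04449
862,0.04475
864,0.04502
866,0.04533
868,0.04568
870,0.04609
872,0.04657
874,0.04713
876,0.04779
878,0.04856
880,0.04945
882,0.05047
884,0.05165
886,0.05299
888,0.0545
890,0.0562
892,0.05811
894,0.06022
896,0.06257
898,0.06516
900,0.068
902,0.07187
904,0.07745
906,0.08462
908,0.09324
910,0.1032
912,0.11436
914,0.1266
916,0.1398
918,0.15382
920,0.16855
922,0.18385
924,0.1996
926,0.21568
928,0.23195
930,0.2483
932,0.26459
934,0.2807
936,0.29651
938,0.31188
940,0.3267
942,0.34083
944,0.35415
946,0.36654
948,0.37786
950,0.388
952,0.39741
954,0.40654
956,0.41523
958,0.42331
960,0.43063
962,0.43701
964,0.4423
966,0.44634
968,0.44896
970,0.45
972,0.44958
974,0.448
976,0.44534
978,0.44169
980,0.43715
982,0.43181
984,0.42576
986,0.4191
988,0.41191
990,0.4043
992,0.39634
994,0.38814
996,0.37979
998,0.37138
1000,0.363
1002,0.3541
1004,0.3442
1006,0.33345
1008,0.32202
1010,0.31009
1012,0.29782
1014,0.28538
1016,0.27294
1018,0.26067
1020,0.24873
1022,0.2373
1024,0.22655
1026,0.21663
1028,0.20773
1030,0.2
1032,0.19319
1034,0.18693
1036,0.18118
1038,0.17593
1040,0.17115
1042,0.16684
1044,0.16296
1046,0.1595
1048,0.15644
1050,0.15377
1052,0.15145
1054,0.14947
1056,0.14781
1058,0.14646
1060,0.14538
1062,0.14457
1064,0.144
1066,0.1436
1068,0.14332
1070,0.14318
1072,0.1432
1074,0.14339
1076,0.14378
1078,0.14437
1080,0.1452
1082,0.14628
1084,0.14762
1086,0.14924
1088,0.15116
1090,0.1534
1092,0.15598
1094,0.15891
1096,0.16221
1098,0.1659
1100,0.17
1102,0.17516
1104,0.18194
1106,0.19027
1108,0.20004
1110,0.21115
1112,0.22351
1114,0.23704
1116,0.25162
1118,0.26717
1120,0.28359
1122,0.30079
1124,0.31867
1126,0.33714
1128,0.3561
1130,0.37546
1132,0.39512
1134,0.41499
1136,0.43497
1138,0.45497
1140,0.47489
1142,0.49463
1144,0.51411
1146,0.53323
1148,0.55189
1150,0.57
1152,0.58846
1154,0.60814
1156,0.62888
1158,0.65056
1160,0.67301
1162,0.6961
1164,0.71967
1166,0.74358
1168,0.76769
1170,0.79184
1172,0.81589
1174,0.83969
1176,0.86311
1178,0.88598
1180,0.90816
1182,0.92951
1184,0.94988
1186,0.96913
1188,0.9871
1190,1.00365
1192,1.01864
1194,1.03192
1196,1.04333
1198,1.05274
1200,1.06
1202,1.06428
1204,1.06512
1206,1.06294
1208,1.05814
1210,1.05113
1212,1.04233
1214,1.03214
1216,1.02098
1218,1.00925
1220,0.99737
1222,0.98574
1224,0.97478
1226,0.9649
1228,0.9565
1230,0.95
1232,0.94426
1234,0.93796
1236,0.93123
1238,0.92421
1240,0.91703
1242,0.90982
1244,0.90271
1246,0.89584
1248,0.88934
1250,0.88333
1252,0.87796
1254,0.87336
1256,0.86965
1258,0.86698
1260,0.86547
1262,0.86525
1264,0.86647
1266,0.86924
1268,0.87371
1270,0.88
1272,0.88739
1274,0.89523
1276,0.90376
1278,0.91323
1280,0.92389
1282,0.93598
1284,0.94975
1286,0.96545
1288,0.98332
1290,1.00361
1292,1.02657
1294,1.05244
1296,1.08147
1298,1.11391
1300,1.15
1302,1.18316
1304,1.20756
1306,1.22463
1308,1.23577
1310,1.2424
1312,1.24592
1314,1.24775
1316,1.2493
1318,1.25198
1320,1.2572
1322,1.26637
1324,1.28091
1326,1.30221
1328,1.33171
1330,1.3708
1332,1.4209
1334,1.48342
1336,1.55977
1338,1.65136
1340,1.7596
1342,1.88591
1344,2.03169
1346,2.19836
1348,2.38732
1350,2.6
1352,2.83256
1354,3.08011
1356,3.34241
1358,3.61924
1360,3.9104
1362,4.21565
1364,4.53478
1366,4.86756
1368,5.21377
1370,5.5732
1372,5.94562
1374,6.33081
1376,6.72855
1378,7.13862
1380,7.5608
1382,7.99487
1384,8.4406
1386,8.89778
1388,9.36619
1390,9.8456
1392,10.3358
1394,10.83655
1396,11.34765
1398,11.86888
1400,12.4
1402,12.95432
1404,13.54292
1406,14.1623
1408,14.80896
1410,15.47937
1412,16.17004
1414,16.87744
1416,17.59808
1418,18.32843
1420,19.065
1422,19.80427
1424,20.54272
1426,21.27686
1428,22.00316
1430,22.71813
1432,23.41824
1434,24.09999
1436,24.75988
1438,25.39438
1440,26
1442,26.6232
1444,27.2616
1446,27.8384
1448,28.2768
1450,28.5
1452,28.55824
1454,28.55552
1456,28.49568
1458,28.38256
1460,28.22
1462,28.01184
1464,27.76192
1466,27.47408
1468,27.15216
1470,26.8
1472,26.42144
1474,26.02032
1476,25.60048
1478,25.16576
1480,24.72
1482,24.26704
1484,23.81072
1486,23.35488
1488,22.90336
1490,22.46
1492,22.02864
1494,21.61312
1496,21.21728
1498,20.84496
1500,20.5
1502,20.16676
1504,19.82751
1506,19.48296
1508,19.13382
1510,18.7808
1512,18.42461
1514,18.06597
1516,17.70558
1518,17.34415
1520,16.9824
1522,16.62103
1524,16.26076
1526,15.90228
1528,15.54633
1530,15.1936
1532,14.84481
1534,14.50066
1536,14.16187
1538,13.82915
1540,13.5032
1542,13.18474
1544,12.87448
1546,12.57313
1548,12.2814
1550,12
1552,11.72587
1554,11.45559
1556,11.18934
1558,10.92728
1560,10.6696
1562,10.41646
1564,10.16804
1566,9.92451
1568,9.68604
1570,9.4528
1572,9.22497
1574,9.00273
1576,8.78623
1578,8.57567
1580,8.3712
1582,8.173
1584,7.98125
1586,7.79612
1588,7.61778
1590,7.4464
1592,7.28216
1594,7.12522
1596,6.97577
1598,6.83397
1600,6.7
1602,6.5752
1604,6.46048
1606,6.35536
1608,6.25936
1610,6.172
1612,6.0928
1614,6.02128
1616,5.95696
1618,5.89936
1620,5.848
1622,5.8024
1624,5.76208
1626,5.72656
1628,5.69536
1630,5.668
1632,5.644
1634,5.62288
1636,5.60416
1638,5.58736
1640,5.572
1642,5.5576
1644,5.54368
1646,5.52976
1648,5.51536
1650,5.5
1652,5.48612
1654,5.47636
1656,5.47049
1658,5.46831
1660,5.4696
1662,5.47416
1664,5.48177
1666,5.49222
1668,5.5053
1670,5.5208
1672,5.53851
1674,5.55821
1676,5.57971
1678,5.60277
1680,5.6272
1682,5.65278
1684,5.6793
1686,5.70655
1688,5.73432
1690,5.7624
1692,5.79057
1694,5.81863
1696,5.84636
1698,5.87356
1700,5.9
1702,5.92655
1704,5.95419
1706,5.98287
1708,6.01255
1710,6.0432
1712,6.07478
1714,6.10724
1716,6.14056
1718,6.17469
1720,6.2096
1722,6.24524
1724,6.28158
1726,6.31858
1728,6.3562
1730,6.3944
1732,6.43315
1734,6.4724
1736,6.51212
1738,6.55226
1740,6.5928
1742,6.63369
1744,6.67489
1746,6.71637
1748,6.75809
1750,6.8
1752,6.84247
1754,6.88584
1756,6.93006
1758,6.97507
1760,7.0208
1762,7.06721
1764,7.11423
1766,7.1618
1768,7.20988
1770,7.2584
1772,7.3073
1774,7.35653
1776,7.40603
1778,7.45574
1780,7.5056
1782,7.55556
1784,7.60556
1786,7.65553
1788,7.70543
1790,7.7552
1792,7.80477
1794,7.8541
1796,7.90312
1798,7.95177
1800,8
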