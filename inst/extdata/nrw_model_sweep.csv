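J,beta_men,beta_women,sigma2_men,sigma2_women,BIC_men,BIC_women,BIC2_men,BIC2_women
1,0.2560,0.1673,0.8969,0.5147,1503.98,1497.21,1513.12,1506.34
2,0.2560,0.1673,0.4407,0.2593,1499.24,1359.64,1514.46,1374.86
3,0.2560,0.1673,0.3079,0.2088,1455.63,1294.24,1476.94,1315.56
4,0.2560,0.1673,0.2651,0.1882,1434.90,1264.26,1462.30,1291.66
5,0.2560,0.1673,0.2308,0.1760,1396.11,1246.16,1429.60,1279.65
6,0.2560,0.1673,0.2114,0.1655,1369.02,1239.95,1408.60,1279.53
7,0.2560,0.1673,0.2045,0.1594,1364.20,1232.36,1409.87,1278.02
8,0.2560,0.1673,0.2014,0.1566,1365.88,1229.81,1417.63,1281.57
9,0.2560,0.1673,0.2014,0.1547,1373.86,1232.48,1431.70,1290.33
10,0.2560,0.1673,0.2012,0.1545,1381.61,1240.11,1445.55,1304.05
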