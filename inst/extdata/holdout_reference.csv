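actual,forecast
1447.519173,1587.9
1374.982592,1273.6
1502.487,1632
1453.230569,1274.9
1506.05569,1453.0896
1489.364,1420.734
2127.725793,2103.7928
1453.230569,1423.2688
1467.790541,1321.5
1273.594991,1320.8
1447.519173,1360.8
1841.729358,1380.6
1374.982592,1592.9
1619.554,1473.6
1597.995,1586.4
1502.487,1394.3
1506.05569,1454.8
1465.664,1278.7
1477.273482,1376.9
1631.990382,1368.2
1447.519173,1300.50
1597.995,1560.90
1320.794994,1317.00
1453.230569,1699.80
1841.729358,1571.40
1489.364,1315.70
1320.794994,1274.00
1546.336,1285.30
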