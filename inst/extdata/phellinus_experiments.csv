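ph,temperature_C,initial_volume_ml,rotation_speed_rpm,inoculum_pct,seed_age_d,fermentation_time,yield_ug_ml,group,label,synthetic
1,28,100,140,5,8,8,45.929,ph,0,FALSE
2,28,100,140,5,8,8,35.077,ph,0,FALSE
3,28,100,140,5,8,8,45.654,ph,0,FALSE
4,28,100,140,5,8,8,534.39,ph,0,FALSE
5,28,100,140,5,8,8,702.81,ph,0,FALSE
6,28,100,140,5,8,8,1467.790541,ph,1,FALSE
7,28,100,140,5,8,8,189.20,ph,0,FALSE
8,28,100,140,5,8,8,91.049,ph,0,FALSE
9,28,100,140,5,8,8,60.841,ph,0,FALSE
10,28,100,140,5,8,8,57.225,ph,0,FALSE
11,28,100,140,5,8,8,43.238,ph,0,FALSE
12,28,100,140,5,8,8,36.288,ph,0,FALSE
13,28,100,140,5,8,8,20.943,ph,0,FALSE
14,28,100,140,5,8,8,22.306,ph,0,FALSE
6,28,40,140,5,8,8,508.495,volume,0,FALSE
6,28,60,140,5,8,8,900.662,volume,0,FALSE
6,28,80,140,5,8,8,1273.594991,volume,1,FALSE
6,28,100,140,5,8,8,1153.937,volume,0,FALSE
6,28,120,140,5,8,8,1123.330,volume,0,FALSE
6,28,140,140,5,8,8,1088.064,volume,0,FALSE
6,28,100,140,2,8,8,546.609,inoculum,0,FALSE
6,28,100,140,4,8,8,606.345,inoculum,0,FALSE
6,28,100,140,6,8,8,1320.794994,inoculum,1,FALSE
6,28,100,140,8,8,8,1447.519173,inoculum,1,FALSE
6,28,100,140,10,8,8,1841.729358,inoculum,1,FALSE
6,28,100,140,12,8,8,1631.990382,inoculum,1,FALSE
6,28,100,140,14,8,8,481.1172,inoculum,0,FALSE
6,28,100,140,16,8,8,449.5187,inoculum,0,FALSE
6,25,40,140,10,8,8,1145.669,temperature,0,FALSE
6,30,60,140,10,8,8,1506.05569,temperature,1,FALSE
6,35,80,140,10,8,8,1374.982592,temperature,1,FALSE
6,40,100,140,10,8,8,875.341,temperature,0,FALSE
6,28,100,150,2,8,1,56.606,time,0,FALSE
6,28,100,150,4,8,2,83.435,time,0,FALSE
6,28,100,150,6,8,3,303.984,time,0,FALSE
6,28,100,150,8,8,4,449.919,time,0,FALSE
6,28,100,150,10,8,5,777.331,time,0,FALSE
6,28,100,150,12,8,6,1103.987,time,0,FALSE
6,28,100,150,14,8,7,1619.554,time,1,FALSE
6,28,100,150,16,8,8,1597.995,time,1,FALSE
6,28,100,150,10,8,9,1546.336,time,1,FALSE
6,28,100,150,10,8,10,1502.487,time,1,FALSE
6,28,100,150,10,8,11,1489.364,time,1,FALSE
6,28,100,150,10,8,12,1465.664,time,1,FALSE
6,28,100,150,2,4,1,1272.384,seed_age,0,FALSE
6,28,100,150,4,5,2,1453.230569,seed_age,1,FALSE
6,28,100,150,6,6,3,1428.025,seed_age,1,FALSE
6,28,100,150,8,7,4,1477.273482,seed_age,1,FALSE
6,28,100,150,10,8,5,2164.513,seed_age,1,FALSE
6,28,100,150,12,9,6,2127.725793,seed_age,1,FALSE
6,28,100,150,14,10,7,1741.498,seed_age,1,FALSE
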