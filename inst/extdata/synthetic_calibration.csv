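frequency_hz,rate_40uV,rate_355uV
0.05,0.2953,0.3013
0.1,0.5247,0.5353
0.2,0.7731,0.7887
0.30000000000000004,0.8735,0.8912
0.4,0.9192,0.9378
0.5,0.9429,0.9619
0.6,0.9566,0.9759
0.7000000000000001,0.9651,0.9846
0.8,0.9708,0.9904
0.9,0.9747,0.9944
1,0.9776,0.9973
1.1,0.9797,0.9995
1.2000000000000002,0.9813,1.0011
1.3000000000000003,0.9826,1.0024
1.4000000000000001,0.9836,1.0035
1.5000000000000002,0.9844,1.0043
1.6,0.9851,1.005
1.7000000000000002,0.9856,1.0056
1.8000000000000003,0.9861,1.006
1.9000000000000001,0.9865,1.0064
2,0.9868,1.0068
3,0.9886,1.0086
4,0.9892,1.0092
5,0.9895,1.0095
6,0.9896,1.0096
7,0.9897,1.0097
8,0.9898,1.0098
9,0.9898,1.0098
10,0.9898,1.0098
11,0.9899,1.0099
12,0.9899,1.0099
13,0.9899,1.0099
14,0.9898,1.0098
15,0.9898,1.0098
16,0.9898,1.0098
17,0.9898,1.0098
18,0.9897,1.0097
19,0.9897,1.0096
20,0.9896,1.0096
30,0.9881,1.008
40,0.9839,1.0038
50,0.9754,0.9951
60,0.9604,0.9798
70,0.9372,0.9562
80,0.9047,0.9229
90,0.8629,0.8803
100,0.8132,0.8296
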