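set,direction,component,delta_max,r_hat_sq
1,radial,reaction,-11.78,0
1,theta,aniso,30.44,0.81
1,theta,fraction,-0.033,0.87
1,theta,iso,2.42,0.88
1,theta,total,44.65,0.58
1,z,aniso,5.41,0.96
1,z,fraction,0.144,0.2
1,z,iso,6.89,NA
1,z,total,24.09,0.66
2,radial,reaction,-8.93,0
2,theta,aniso,2.46,1
2,theta,fraction,-0.015,1
2,theta,iso,1.42,1
2,theta,total,12.8,0.99
2,z,aniso,-6.12,0.99
2,z,fraction,0.083,0.95
2,z,iso,4.66,NA
2,z,total,7.47,1
3,radial,reaction,-14.27,0
3,theta,aniso,75.82,0
3,theta,fraction,-0.015,1
3,theta,iso,0.14,1
3,theta,total,90.23,0
3,z,aniso,29.51,0
3,z,fraction,0.129,0.94
3,z,iso,7.22,NA
3,z,total,51,0
4,radial,reaction,-12.87,0
4,theta,aniso,29.99,0.46
4,theta,fraction,-0.016,1
4,theta,iso,-0.44,1
4,theta,total,42.44,0.18
4,z,aniso,7.42,0.86
4,z,fraction,0.017,1
4,z,iso,-5.91,NA
4,z,total,14.37,0.11
5,radial,reaction,-10.36,0
5,theta,aniso,15.13,0.98
5,theta,fraction,-0.03,0.85
5,theta,iso,2.56,0.86
5,theta,total,28.05,0.94
5,z,aniso,-1.93,1
5,z,fraction,0.121,0.51
5,z,iso,6.86,NA
5,z,total,15.79,0.96
6,radial,reaction,-15.78,0
6,theta,aniso,50.54,0
6,theta,fraction,0.025,1
6,theta,iso,-3.93,0.99
6,theta,total,62.39,0
6,z,aniso,17.67,0.28
6,z,fraction,0.08,1
6,z,iso,4.44,NA
6,z,total,37.89,0
7,radial,reaction,-12.66,0
7,theta,aniso,52.98,0.44
7,theta,fraction,-0.042,0
7,theta,iso,2.79,0
7,theta,total,68.43,0
7,z,aniso,15.75,0.8
7,z,fraction,0.198,0
7,z,iso,10.34,NA
7,z,total,38.75,0.06
8,radial,reaction,-12.79,0
8,theta,aniso,51.51,0.73
8,theta,fraction,-0.005,0
8,theta,iso,0.52,0
8,theta,total,64.81,0.52
8,z,aniso,15.49,0.9
8,z,fraction,0.189,0
8,z,iso,11.88,NA
8,z,total,40.15,0.59
9,radial,reaction,-13.81,0
9,theta,aniso,103.36,0
9,theta,fraction,-0.005,0
9,theta,iso,0.67,0
9,theta,total,117.84,0
9,z,aniso,40.35,0.39
9,z,fraction,0.181,0
9,z,iso,14.66,NA
9,z,total,68.82,0
10,radial,reaction,-14.67,0
10,theta,aniso,80.44,0
10,theta,fraction,-0.007,0
10,theta,iso,0.19,0
10,theta,total,95.29,0
10,z,aniso,31.1,0
10,z,fraction,0.256,0
10,z,iso,12.75,NA
10,z,total,58.51,0
11,radial,reaction,-10.99,0
11,theta,aniso,10.92,0.99
11,theta,fraction,-0.006,0
11,theta,iso,0.18,0
11,theta,total,22.09,0.95
11,z,aniso,-2.81,1
11,z,fraction,0.255,0
11,z,iso,11.41,NA
11,z,total,19.59,0.97
12,radial,reaction,-10.36,0
12,theta,aniso,9.65,1
12,theta,fraction,-0.001,0.23
12,theta,iso,0.2,0
12,theta,total,20.21,0.98
12,z,aniso,-3.83,1
12,z,fraction,0.149,0
12,z,iso,8.77,NA
12,z,total,15.3,0.99
13,radial,reaction,-9.54,0
13,theta,aniso,2.26,1
13,theta,fraction,-0.002,0
13,theta,iso,0.15,0
13,theta,total,11.95,0.99
13,z,aniso,-6.9,0.99
13,z,fraction,0.177,0
13,z,iso,8.89,NA
13,z,total,11.53,1
14,radial,reaction,-13.28,0
14,theta,aniso,35.68,0.67
14,theta,fraction,-0.01,0
14,theta,iso,0.42,0
14,theta,total,49.37,0.11
14,z,aniso,9.34,0.9
14,z,fraction,0.299,0
14,z,iso,12.01,NA
14,z,total,34.63,0
15,radial,reaction,-7.39,0
15,theta,aniso,-2.77,1
15,theta,fraction,-0.025,1
15,theta,iso,3.28,0.99
15,theta,total,7.91,1
15,z,aniso,-8.41,0.99
15,z,fraction,-0.004,1
15,z,iso,-4.02,NA
15,z,total,-5.06,1
16,radial,reaction,-8.03,0
16,theta,aniso,-1.15,1
16,theta,fraction,-0.013,1
16,theta,iso,1.4,1
16,theta,total,8.27,1
16,z,aniso,-7.16,0.99
16,z,fraction,0.015,1
16,z,iso,-1.52,NA
16,z,total,-0.81,1
17,radial,reaction,-4.88,0
17,theta,aniso,-0.85,1
17,theta,fraction,-0.013,1
17,theta,iso,3.74,1
17,theta,total,8.04,0.99
17,z,aniso,-5.16,0.97
17,z,fraction,0.066,0.96
17,z,iso,10.04,NA
17,z,total,9.8,1
18,radial,reaction,-7.46,0.95
18,theta,aniso,-0.54,1
18,theta,fraction,-0.003,1
18,theta,iso,0.99,1
18,theta,total,8.03,1
18,z,aniso,-5.38,0.97
18,z,fraction,0.02,0.99
18,z,iso,-7.72,NA
18,z,total,-5.64,1
19,radial,reaction,-7.02,0.51
19,theta,aniso,-0.73,1
19,theta,fraction,-0.004,1
19,theta,iso,1.25,1
19,theta,total,8.02,0.99
19,z,aniso,-5.94,0.93
19,z,fraction,0.025,0.96
19,z,iso,-8.96,NA
19,z,total,-7.91,1
20,radial,reaction,-6.53,0.83
20,theta,aniso,-0.66,1
20,theta,fraction,-0.003,1
20,theta,iso,1.99,1
20,theta,total,8.01,1
20,z,aniso,-5.85,0.97
20,z,fraction,0.023,0.98
20,z,iso,-2.08,NA
20,z,total,-1.44,1
21,radial,reaction,-7.13,0.84
21,theta,aniso,-0.78,1
21,theta,fraction,-0.006,1
21,theta,iso,1.49,1
21,theta,total,8.11,1
21,z,aniso,-5.16,0.99
21,z,fraction,0.041,1
21,z,iso,2.54,NA
21,z,total,4.67,1
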