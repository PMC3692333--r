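relationship,row,k0,k1,k2,k3,k4,k5,k6,k7,k8,k9,k10,k11,k12,k13,k14,k15
parent,count,10000,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
parent,cumulative,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000
parent,rate_center,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98
parent,rate_halfwidth,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03
uncle,count,54,301,935,1763,2210,2039,1502,752,303,106,26,9,0,0,0,0
uncle,cumulative,54,355,1290,3053,5263,7302,8804,9556,9859,9965,9991,10000,10000,10000,10000,10000
uncle,rate_center,0.56,3.57,12.91,30.54,52.63,73.01,88.02,95.54,98.57,99.63,99.89,99.98,99.98,99.98,99.98,99.98
uncle,rate_halfwidth,0.15,0.36,0.66,0.9,0.98,0.87,0.64,0.4,0.23,0.12,0.06,0.03,0.03,0.03,0.03,0.03
sibling,count,49,377,1063,1879,2244,2016,1326,655,271,91,25,4,0,0,0,0
sibling,cumulative,49,426,1489,3368,5612,7628,8954,9609,9880,9971,9996,10000,10000,10000,10000,10000
sibling,rate_center,0.51,4.28,14.9,33.69,56.12,76.27,89.52,96.07,98.78,99.69,99.94,99.98,99.98,99.98,99.98,99.98
sibling,rate_halfwidth,0.14,0.4,0.7,0.93,0.97,0.83,0.6,0.38,0.22,0.11,0.05,0.03,0.03,0.03,0.03,0.03
half_sibling,count,44,306,915,1693,2302,2071,1518,734,291,101,23,2,0,0,0,0
half_sibling,cumulative,44,350,1265,2958,5260,7331,8849,9583,9874,9975,9998,10000,10000,10000,10000,10000
half_sibling,rate_center,0.46,3.52,12.66,29.59,52.6,73.3,88.47,95.81,98.72,99.73,99.96,99.98,99.98,99.98,99.98,99.98
half_sibling,rate_halfwidth,0.13,0.36,0.65,0.89,0.98,0.87,0.63,0.39,0.22,0.1,0.04,0.03,0.03,0.03,0.03,0.03
grandparent,count,36,315,939,1668,2170,2114,1489,808,337,89,30,5,0,0,0,0
grandparent,cumulative,36,351,1290,2958,5128,7242,8731,9539,9876,9965,9995,10000,10000,10000,10000,10000
grandparent,rate_center,0.38,3.53,12.91,29.59,51.28,72.41,87.3,95.37,98.74,99.63,99.93,99.98,99.98,99.98,99.98,99.98
grandparent,rate_halfwidth,0.12,0.36,0.66,0.89,0.98,0.88,0.65,0.41,0.22,0.12,0.05,0.03,0.03,0.03,0.03,0.03
cousin,count,1,20,97,318,836,1457,1944,1985,1649,1020,471,147,45,10,0,0
cousin,cumulative,1,21,118,436,1272,2729,4673,6658,8307,9327,9798,9945,9990,10000,10000,10000
cousin,rate_center,0.03,0.23,1.2,4.38,12.73,27.3,46.73,66.57,83.06,93.25,97.96,99.43,99.88,99.98,99.98,99.98
cousin,rate_halfwidth,0.03,0.09,0.21,0.4,0.65,0.87,0.98,0.92,0.74,0.49,0.28,0.15,0.07,0.03,0.03,0.03
random_man,count,0,1,3,14,82,245,655,1251,1913,2091,1818,1160,548,177,39,3
random_man,cumulative,0,1,4,18,100,345,1000,2251,4164,6255,8073,9233,9781,9958,9997,10000
random_man,rate_center,0.02,0.03,0.06,0.2,1.02,3.47,10.02,22.52,41.64,62.54,80.72,92.31,97.79,99.56,99.95,99.98
random_man,rate_halfwidth,0.03,0.03,0.05,0.09,0.2,0.36,0.59,0.82,0.97,0.95,0.77,0.52,0.29,0.13,0.04,0.03
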