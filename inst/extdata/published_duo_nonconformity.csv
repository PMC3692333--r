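relationship,row,k0,k1,k2,k3,k4,k5,k6,k7,k8,k9,k10,k11,k12,k13,k14,k15
parent,count,10000,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
parent,cumulative,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000,10000
parent,rate_center,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98
parent,rate_halfwidth,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03
sibling,count,1902,3268,2790,1400,493,121,20,6,0,0,0,0,0,0,0,0
sibling,cumulative,1902,5170,7960,9360,9853,9974,9994,10000,10000,10000,10000,10000,10000,10000,10000,10000
sibling,rate_center,19.03,51.7,79.59,93.58,98.51,99.72,99.92,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98,99.98
sibling,rate_halfwidth,0.77,0.98,0.79,0.48,0.24,0.1,0.06,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03,0.03
grandparent,count,279,1137,2063,2582,1987,1185,546,164,43,10,3,1,0,0,0,0
grandparent,cumulative,279,1416,3479,6061,8048,9233,9779,9943,9986,9996,9999,10000,10000,10000,10000,10000
grandparent,rate_center,2.81,14.17,34.8,60.61,80.47,92.31,97.77,99.41,99.84,99.94,99.97,99.98,99.98,99.98,99.98,99.98
grandparent,rate_halfwidth,0.32,0.68,0.93,0.96,0.78,0.52,0.29,0.15,0.08,0.05,0.03,0.03,0.03,0.03,0.03,0.03
uncle,count,276,1162,2127,2545,2015,1142,514,170,43,6,0,0,0,0,0,0
uncle,cumulative,276,1438,3565,6110,8125,9267,9781,9951,9994,10000,10000,10000,10000,10000,10000,10000
uncle,rate_center,2.78,14.39,35.66,61.1,81.24,92.65,97.79,99.49,99.92,99.98,99.98,99.98,99.98,99.98,99.98,99.98
uncle,rate_halfwidth,0.32,0.69,0.94,0.96,0.77,0.51,0.29,0.14,0.06,0.03,0.03,0.03,0.03,0.03,0.03,0.03
half_sibling,count,256,1148,2110,2567,1980,1205,498,180,46,8,2,0,0,0,0,0
half_sibling,cumulative,256,1404,3514,6081,8061,9266,9764,9944,9990,9998,10000,10000,10000,10000,10000,10000
half_sibling,rate_center,2.58,14.05,35.15,60.81,80.6,92.64,97.62,99.42,99.88,99.96,99.98,99.98,99.98,99.98,99.98,99.98
half_sibling,rate_halfwidth,0.31,0.68,0.94,0.96,0.78,0.51,0.3,0.15,0.07,0.04,0.03,0.03,0.03,0.03,0.03,0.03
cousin,count,49,209,726,1456,2067,2206,1762,909,410,154,43,8,1,0,0,0
cousin,cumulative,49,258,984,2440,4507,6713,8475,9384,9794,9948,9991,9999,10000,10000,10000,10000
cousin,rate_center,0.51,2.6,9.86,24.41,45.07,67.12,84.74,93.82,97.92,99.46,99.89,99.97,99.98,99.98,99.98,99.98
cousin,rate_halfwidth,0.14,0.31,0.58,0.84,0.98,0.92,0.7,0.47,0.28,0.14,0.06,0.03,0.03,0.03,0.03,0.03
random_man,count,2,32,133,432,991,1694,2113,1948,1447,762,321,97,23,3,2,0
random_man,cumulative,2,34,167,599,1590,3284,5397,7345,8792,9554,9875,9972,9995,9998,10000,10000
random_man,rate_center,0.04,0.36,1.69,6.01,15.91,32.85,53.97,73.44,87.9,95.52,98.73,99.7,99.93,99.96,99.98,99.98
random_man,rate_halfwidth,0.04,0.12,0.25,0.47,0.72,0.92,0.98,0.87,0.64,0.41,0.22,0.11,0.05,0.04,0.03,0.03
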