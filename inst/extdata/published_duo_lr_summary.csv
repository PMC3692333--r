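relationship,n_nonexclusion,min_log_lr,min_prob,max_log_lr,max_prob,mean_log_lr,half_width,mean_prob
parent,10000,1.4845,96.8268,11.4087,100,5.0207,0.0247,99.999
sibling,1902,1.2337,94.4836,10.4002,100,5.601,0.0577,99.9997
grandparent,279,1.5582,97.3088,7.9826,100,4.0263,0.1346,99.9906
uncle,276,1.6478,97.7994,8.5425,100,4.2644,0.1412,99.9946
half_sibling,256,1.0975,92.6019,6.8732,100,4.215,0.1343,99.9939
cousin,49,0.788,85.9897,6.1611,99.9999,3.4479,0.3127,99.9644
random_man,2,2.8206,99.8491,3.2468,99.9434,3.0337,2.7075,99.9076
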