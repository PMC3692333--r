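relationship,n_nonexclusion,min_log_lr,min_prob,max_log_lr,max_prob,mean_log_lr,half_width,mean_prob
parent,10000,4.0061,99.9901,16.0957,100,7.4741,0.0266,100
uncle,54,4.1748,99.9933,9.3911,100,6.7822,0.2991,100
sibling,49,4.9335,99.9988,9.9194,100,6.9927,0.3519,100
half_sibling,44,4.9754,99.9989,10.4723,100,7.1267,0.4025,100
grandparent,36,5.0455,99.9991,8.6544,100,6.7147,0.3326,100
cousin,1,7.6185,100,7.6185,100,7.6185,NA,100
random_man,0,NA,NA,NA,NA,NA,NA,NA
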