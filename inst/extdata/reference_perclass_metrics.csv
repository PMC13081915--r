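category,method,precision,recall,f1,support
DO,baseline,0.9351,0.9514,0.9432,4421
DO,two_step,0.9873,0.9810,0.9841,4421
E,baseline,0.7282,0.8242,0.7732,91
E,two_step,0.9158,0.9560,0.9355,91
ES,baseline,0.8902,0.8196,0.8535,1009
ES,two_step,0.9513,0.9485,0.9499,1009
G,baseline,0.6997,0.6238,0.6596,646
G,two_step,0.9299,0.9443,0.9370,646
R,baseline,0.5228,0.7574,0.6186,136
R,two_step,0.8301,0.9338,0.8789,136
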