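true_bin,pred_lt5,pred_5_10,pred_10_15,pred_15_30,pred_ge30
lt5,71,0,0,0,0
5_10,84,27,1,0,0
10_15,30,54,8,1,0
15_30,25,87,65,39,0
ge30,5,23,29,57,47
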