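threshold,direction,hemisphere,cv_total,ct_only,sa_only,ct_and_sa
p<0.05,case_lt_control,left,40736,94,35529,3059
p<0.05,case_lt_control,right,37381,264,28547,6386
p<0.05,case_gt_control,left,0,0,0,0
p<0.05,case_gt_control,right,6828,2330,0,0
p<0.01,case_lt_control,left,22445,67,19331,481
p<0.01,case_lt_control,right,15797,30,13757,542
p<0.01,case_gt_control,left,0,0,0,0
p<0.01,case_gt_control,right,1787,0,0,0
p<0.001,case_lt_control,left,11183,22,9924,42
p<0.001,case_lt_control,right,5429,0,4037,0
p<0.001,case_gt_control,left,0,0,0,0
p<0.001,case_gt_control,right,0,0,0,0
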