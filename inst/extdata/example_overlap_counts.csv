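threshold,hemisphere,ct_only,sa_only,both
p<0.05,left,10173,67029,14951
p<0.05,right,12980,61442,21293
p<0.01,left,2604,50061,4898
p<0.01,right,6756,44139,5860
p<0.001,left,529,30876,552
p<0.001,right,1849,27977,590
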