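age_group,state,population_10k
60-64,1,1184
60-64,2,2489
60-64,3,2836
60-64,4,1334
65-69,1,686
65-69,2,1853
65-69,3,1968
65-69,4,984
70-74,1,477
70-74,2,1070
70-74,3,1318
70-74,4,762
75-79,1,361
75-79,2,822
75-79,3,943
75-79,4,506
80+,1,446
80+,2,745
80+,3,863
80+,4,465
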