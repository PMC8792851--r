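year,age_group,state,total_billion
2015,all,1,5.542
2015,all,4,26.112
2035,all,1,10.558
2035,all,2,23.510
2035,all,3,47.344
2035,all,4,48.645
2015,60-64,4,9.853
2015,65-69,4,6.262
2015,70-74,4,4.713
2015,75-79,4,3.695
2015,80+,4,2.738
2035,60-64,4,14.07
2035,65-69,4,12.373
2035,70-74,4,11.20
2035,75-79,4,7.387
2035,80+,4,6.288
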