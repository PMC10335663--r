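time_days,disk_id,Ksv,R0
0,a,0.012,1.881
0,b,0.009,1.948
0,c,0.010,1.930
7,a,0.011,1.776
7,b,0.010,1.875
7,c,0.011,1.877
14,a,0.011,1.727
14,b,0.010,1.839
14,c,0.011,1.825
28,a,0.011,1.722
28,b,0.010,1.828
28,c,0.010,1.805
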