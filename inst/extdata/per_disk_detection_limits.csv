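disk,lod_pct_sat,loq_pct_sat
1,1.15,3.50
2,0.58,1.75
3,1.61,4.88
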