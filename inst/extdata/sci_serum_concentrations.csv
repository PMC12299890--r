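subject_id,time_h,conc_mg_per_L
1,0,BLQ
1,0.25,BLQ
1,0.5,1
1,1,1.6
1,1.5,7.2
1,12,BLQ
1,24,BLQ
2,0,BLQ
2,0.25,BLQ
2,0.5,4.6
2,1,5.6
2,1.5,6.2
2,12,BLQ
2,24,BLQ
3,0,BLQ
3,0.25,BLQ
3,0.5,5.6
3,1,6.8
3,1.5,4.4
3,12,BLQ
3,24,BLQ
4,2,3.2
4,4,0.6
4,8,0.4
4,36,BLQ
4,48,BLQ
5,2,3.8
5,4,6.1
5,8,0.2
5,36,BLQ
5,48,BLQ
6,2,5.4
6,4,3.6
6,8,0.4
6,36,BLQ
6,48,BLQ
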