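subject_id,k_per_h
1,2.521
2,0.01387
3,0.0276
4,0.9102
5,0.161
6,0.2861
pooled,0.0689
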