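rater,n_correct,n_total
1,55,100
2,56,100
3,42,100
4,59,100
5,53,100
6,49,100
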