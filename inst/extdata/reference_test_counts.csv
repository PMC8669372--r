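n_test,p1,p3,m1,m3
167,52,4,83,1
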