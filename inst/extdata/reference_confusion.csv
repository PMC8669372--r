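method,actual,A1,A2,A3,A4
svm,A1,37,0,0,0
svm,A2,0,24,0,0
svm,A3,1,0,38,4
svm,A4,0,3,2,58
topsis,A1,37,0,0,0
topsis,A2,0,24,0,0
topsis,A3,0,0,41,2
topsis,A4,0,0,1,62
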