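truth,W,N1,N2,N3,REM
W,57878,2121,346,32,370
N1,2902,9061,5713,36,1854
N2,412,2682,56410,1265,2078
N3,44,11,2326,9457,16
REM,343,1312,1805,5,20021
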