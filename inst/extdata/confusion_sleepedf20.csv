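truth,W,N1,N2,N3,REM
W,8652,224,98,15,150
N1,454,1096,657,5,610
N2,106,206,16525,411,673
N3,17,0,646,4768,4
REM,91,154,512,3,6955
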