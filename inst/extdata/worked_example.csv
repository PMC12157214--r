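sample_id,label,B1,B2,B3,B4
S1,0,1.28,3.24,0.32,4.56
S2,1,1.73,0.21,2.12,1.12
S3,1,0.50,1.62,0.67,0.45
S4,0,2.31,0.82,1.32,3.65
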