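sample_id,p5c
S1,0.86
S2,0.99
S3,0.93
S4,0.97
S5,1.02
S6,0.96
S7,0.97
S8,1.02
S9,1.02
S10,1.01
S11,1.02
S12,1.06
S13,0.98
S14,0.96
S15,1.05
S16,0.98
S17,1.22
S18,1
S19,0.84
S20,1
S21,1.09
S22,0.88
S23,0.81
S24,0.91
S25,1.25
S26,0.93
S27,1.02
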