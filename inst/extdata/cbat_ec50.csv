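sample_id,ec50_measured,ec50_sd,re_cv,ec50_predicted,re_predicted
S1,0.694,0.007,8,0.701,1
S2,0.641,0.006,0.1,0.639,-0.4
S3,0.585,0.005,8.5,0.58,-0.9
S4,0.661,0.008,16.1,0.673,1.8
S5,0.661,0.007,2.5,0.663,0.3
S6,0.771,0.009,-10.7,0.786,1.9
S7,0.679,0.008,5.7,0.69,1.6
S8,0.712,0.009,-6.2,0.702,-1.4
S9,0.684,0.006,-2,0.678,-0.8
S10,0.649,0.003,3.1,0.62,-4.5
S11,0.736,0.006,-7.4,0.71,-3.6
S12,0.721,0.007,-8.9,0.716,-0.8
S13,0.663,0.006,0.9,0.667,0.6
S14,0.663,0.008,5.1,0.674,1.6
S15,0.63,0.007,1.6,0.626,-0.6
S16,0.729,0.008,-8,0.736,1
S17,0.446,0.002,26.4,0.513,15
S18,0.632,0.006,-6.2,0.622,-1.6
S19,0.753,0.01,-6.7,0.768,2
S20,0.657,0.007,-5.2,0.676,2.9
S21,0.595,0.006,-1.5,0.603,1.3
S22,0.712,0.011,-12.4,0.68,-4.5
S23,0.826,0.012,-14.3,0.803,-2.8
S24,0.694,0.007,3.6,0.698,0.6
S25,0.522,0.005,-23.8,0.434,-16.9
S26,0.602,0.003,18.6,0.619,2.8
S27,0.585,0.005,11.6,0.595,1.7
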