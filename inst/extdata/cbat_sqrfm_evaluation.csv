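sample_id,channel,sf_prime,mf,alpha,grade
S1,250,0.95,84,0.05,3
S2,250,0.98,96.8,0.02,1
S3,250,0.94,101.2,0.06,2
S4,250,0.96,92.1,0.04,2
S5,250,0.99,93.8,0.01,2
S6,250,0.97,101.3,0.03,1
S7,250,0.98,95.2,0.02,1
S8,250,0.98,95.8,0.02,1
S9,250,0.98,104.1,0.02,1
S10,250,0.98,97.2,0.02,1
S11,250,0.97,99.3,0.03,1
S12,250,0.96,100.6,0.04,1
S13,250,0.98,97.6,0.02,1
S14,250,0.98,94.7,0.02,2
S15,250,0.99,103.4,0.01,1
S16,250,0.89,97.3,0.11,3
S17,250,0.87,127.5,0.14,5
S18,250,0.91,81.3,0.09,3
S19,250,0.92,70.4,0.08,5
S20,250,0.88,69.5,0.12,6
S21,250,0.87,102.6,0.13,3
S22,250,0.95,83.9,0.05,3
S23,250,0.9,69,0.1,6
S24,250,0.96,77.6,0.04,4
S25,250,0.87,133.3,0.14,6
S26,250,0.96,89,0.04,3
S27,250,0.98,98.8,0.02,1
S1,276,0.96,86.1,0.05,3
S2,276,0.98,92.9,0.02,2
S3,276,0.97,101.7,0.03,1
S4,276,0.96,82.3,0.04,3
S5,276,0.99,95.1,0.01,1
S6,276,0.96,95,0.04,2
S7,276,0.97,88.5,0.03,3
S8,276,0.98,88.1,0.02,3
S9,276,0.99,99.9,0.01,1
S10,276,0.98,96.7,0.02,1
S11,276,0.99,94.2,0.01,2
S12,276,0.99,100.1,0.02,1
S13,276,0.99,100.2,0.02,1
S14,276,0.98,99.2,0.02,1
S15,276,0.98,107.2,0.02,2
S16,276,0.9,103.9,0.1,2
S17,276,0.86,116.4,0.14,3
S18,276,0.91,82,0.09,3
S19,276,0.87,71.1,0.13,5
S20,276,0.91,89.2,0.09,3
S21,276,0.89,109.9,0.11,3
S22,276,0.96,85.9,0.04,3
S23,276,0.91,72.3,0.09,5
S24,276,0.96,79.9,0.04,4
S25,276,0.85,122.1,0.15,4
S26,276,0.97,89.6,0.03,3
S27,276,0.98,99.3,0.03,1
S1,330,0.97,80.9,0.03,3
S2,330,0.99,92.1,0.01,2
S3,330,0.97,92.5,0.03,2
S4,330,0.98,80.8,0.02,3
S5,330,0.99,97,0,1
S6,330,0.99,87.6,0,3
S7,330,0.99,86.5,0.01,3
S8,330,1,97.4,0,1
S9,330,0.99,98.15,0.005,1
S10,330,0.98,102.1,0.02,1
S11,330,0.99,91.5,0.01,2
S12,330,1,100.7,0,1
S13,330,1,98.9,0,1
S14,330,0.99,101.1,0.01,1
S15,330,0.99,95.2,0.02,1
S16,330,0.98,93.9,0.02,2
S17,330,0.97,185.1,0.03,8
S18,330,0.89,81,0.12,3
S19,330,0.99,79.1,0.02,4
S20,330,0.88,82.4,0.12,3
S21,330,0.96,148.1,0.04,7
S22,330,0.99,78.5,0.01,4
S23,330,0.96,72.9,0.04,5
S24,330,0.99,81.1,0.01,3
S25,330,0.96,190.3,0.04,8
S26,330,0.99,88.5,0.01,3
S27,330,0.98,95.9,0.02,1
S1,360,0.97,81.2,0.03,3
S2,360,0.97,86.9,0.03,3
S3,360,0.85,90,0.15,4
S4,360,0.98,91.3,0.02,2
S5,360,0.98,96.8,0.02,1
S6,360,0.98,90.3,0.02,2
S7,360,0.99,85.2,0.02,3
S8,360,0.98,90.2,0.02,2
S9,360,0.97,85.6,0.03,3
S10,360,0.98,96.6,0.02,1
S11,360,0.97,82,0.03,3
S12,360,0.98,90.1,0.03,2
S13,360,0.99,99.2,0.01,1
S14,360,0.99,98,0.01,1
S15,360,0.99,96.8,0.01,1
S16,360,0.97,92.9,0.03,2
S17,360,0.94,145.9,0.06,7
S18,360,0.88,88.8,0.12,3
S19,360,0.95,79.3,0.05,4
S20,360,0.9,107.6,0.1,2
S21,360,0.97,149.1,0.03,7
S22,360,0.95,91.1,0.05,2
S23,360,0.91,84.1,0.09,3
S24,360,0.95,88.9,0.05,3
S25,360,0.93,144.5,0.07,7
S26,360,0.93,91,0.07,2
S27,360,0.96,85.4,0.04,3
S1,375,0.97,80.6,0.03,3
S2,375,1,94.8,0,2
S3,375,0.98,101.58,0.02,1
S4,375,0.99,92.4,0.01,2
S5,375,0.99,98.7,0.01,1
S6,375,0.97,91.1,0.03,2
S7,375,1,89.2,0,3
S8,375,1,100.6,0,1
S9,375,0.99,100.6,0.01,1
S10,375,0.99,105.3,0.01,2
S11,375,1,97.1,0,1
S12,375,0.99,103.3,0.01,1
S13,375,0.99,98.9,0.01,1
S14,375,0.98,102.9,0.02,1
S15,375,1,97.8,0,1
S16,375,1,97.2,0,1
S17,375,0.95,168.8,0.05,8
S18,375,0.84,83.1,0.16,4
S19,375,0.97,73.1,0.03,5
S20,375,0.85,84.4,0.15,4
S21,375,0.96,134,0.04,6
S22,375,1,76.7,0,4
S23,375,0.96,72.1,0.04,5
S24,375,0.98,82,0.02,3
S25,375,0.95,172.8,0.05,8
S26,375,0.99,81.1,0.01,3
S27,375,0.99,97.6,0.01,1
S1,integrated,0.96,82.8,0.04,3
S2,integrated,0.98,92.9,0.02,2
S3,integrated,0.94,97.7,0.06,2
S4,integrated,0.97,87.7,0.03,3
S5,integrated,0.99,96,0.01,1
S6,integrated,0.98,93.6,0.02,2
S7,integrated,0.98,89.2,0.02,3
S8,integrated,0.99,94.3,0.01,2
S9,integrated,0.98,98.2,0.02,1
S10,integrated,0.98,99.3,0.02,1
S11,integrated,0.98,93.2,0.02,2
S12,integrated,0.98,99.1,0.02,1
S13,integrated,0.99,98.9,0.01,1
S14,integrated,0.99,98.9,0.01,1
S15,integrated,1,100.5,0.01,1
S16,integrated,0.94,97.3,0.06,2
S17,integrated,0.91,147,0.09,7
S18,integrated,0.89,83.1,0.11,3
S19,integrated,0.94,74.3,0.07,5
S20,integrated,0.89,85.8,0.11,3
S21,integrated,0.93,126.7,0.08,5
S22,integrated,0.97,83.4,0.03,3
S23,integrated,0.93,73.8,0.07,5
S24,integrated,0.97,81.6,0.03,3
S25,integrated,0.91,151.2,0.09,8
S26,integrated,0.97,88.1,0.03,3
S27,integrated,0.98,95.8,0.02,1
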