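bvalue,signal_mean,signal_sd,snr,cnr
0,925.93,10.04,92.26,0.85
200,759.45,7.73,98.27,18.14
400,617.34,5.23,117.98,33.02
600,501.89,4.07,123.30,38.60
800,409.45,3.76,108.85,43.37
1000,332.54,3.43,96.87,43.63
1200,271.42,2.95,92.02,37.78
1400,221.70,2.87,77.36,35.14
1600,181.40,3.01,60.26,30.33
1800,148.13,3.00,49.31,25.76
2000,120.16,2.69,44.70,25.96
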