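d,signal_mean,signal_sd,snr,cnr
0.010,332.54,3.38,98.52,44.02
0.011,332.57,1.57,211.52,128.57
0.012,332.56,1.56,213.38,130.25
0.013,332.55,1.55,214.77,131.32
0.014,332.55,1.54,215.81,131.98
0.015,332.55,1.54,216.60,132.39
0.02,332.56,1.53,217.20,132.63
0.03,332.59,1.52,218.63,132.77
0.04,332.61,1.52,218.92,132.15
0.05,332.61,1.52,219.07,131.87
0.06,332.59,1.51,220.15,132.15
0.07,332.55,1.50,222.47,133.00
0.08,332.50,1.47,225.92,134.34
0.09,332.43,1.44,230.11,135.96
0.10,332.34,1.42,234.31,137.56
0.11,332.25,1.40,237.41,138.71
0.12,332.15,1.40,238.03,138.91
0.13,332.04,1.41,234.90,137.66
0.14,331.94,1.46,227.47,134.68
0.15,331.83,1.53,216.28,130.06
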