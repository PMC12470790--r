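method,bvalue,snr,cnr
none,600,123.30,38.60
none,1000,96.87,43.63
median,1000,150.36,57.67
wiener,1000,185.38,76.84
tv,1000,138.14,53.53
nlm,1000,215.81,131.98
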