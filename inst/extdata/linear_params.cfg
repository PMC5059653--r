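b0 = 0.675
b1 = 0.007
A0 = 0.3
A1 = 0.001
Omega0 = -pi/150
Omega1 = pi/1500
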