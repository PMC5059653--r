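b0 = 0.4475
b1 = 0.1575
A0 = 0.3325
A1 = 0.0225
Omega0 = 3*pi/200
Omega1 = 3*pi/200
C = 0.055
Tbar = 33.75
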