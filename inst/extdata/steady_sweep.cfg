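# steady sweep over the standard temperatures
command = steady
temperatures = 15,20,25,30,35,40
dt = 0.01
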