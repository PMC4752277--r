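# Calibrated in-vivo parameter set (monoxenic mouse gut)
d = 0.25
r = 1.1
k = 4.6e9
x = 0.016
l = 0.8
y = 12.1
a = 2.6e-9
g = 0.19
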