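# Euler-map Neimark-Sacker worked example
r = 3.0609
k = 1.258
alpha = 3.499
a = 0.8559
m = 0.9
beta = 4.8959
rho = 2.9
delta = 0.47122
eta = 0.4681150757612096
p0 = 0.26452580082377936
z0 = 0.7740415103508146
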