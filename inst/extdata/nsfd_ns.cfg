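# NSFD-map Neimark-Sacker worked example
r = 2.4917
k = 0.217
alpha = 0.217
a = 0.217
m = 0.217
beta = 2.09
rho = 0.217
delta = 0.32
eta = 0.4115075
p0 = 0.0442580082377936
z0 = 2.3740415103508146
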