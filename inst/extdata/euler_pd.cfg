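# Euler-map period-doubling worked example
# (reference only: parameters violate the interior-existence condition)
r = 2.9609
k = 1.258
alpha = 3.499
a = 0.9559
m = 0.33
beta = 3.08959
rho = 2.7
delta = 0.57122
eta = 0.73681150757612096
p0 = 1.26452580082377936
z0 = 0.07740415103508146
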