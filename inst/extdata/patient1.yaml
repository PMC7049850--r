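# Reference parameter set "first patient" (human values).
label: patient1
a: 4.31e-01
a1: 1.0e+05
b: 1.02e-09
c: 6.41e-11
c1: 2.0e-01
d: 2.34
e: 2.08e-07
f: 4.12e-02
g: 1.25e-02
g_i: 2.0e+07
h: 2.02e+07
j: 2.49e-02
k: 3.66e+07
K_T: 9.0e-01
K_N: 6.0e-01
K_L: 6.0e-01
K_C: 6.0e-01
l: 2.09
m: 2.04e-01
p: 3.42e-06
p_i: 1.25e-01
q: 1.42e-06
r1: 1.1e-07
r2: 6.5e-11
s: 8.39e-02
u: 3.0e-10
alpha: 7.5e+08
alpha1: 1.0e+03
alpha2: 1.0e+03
beta: 1.2e-02
beta1: 8.35e-01
beta2: 5.4
gamma: 9.0e-01
mu1: 1.0e-01
mu_i: 10.0
delta2: 1.0e-07
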