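# Reference parameter set "second patient" (human values).
label: patient2
a: 4.31e-01
a1: 1.0e+05
b: 1.02e-09
c: 6.41e-11
c1: 2.0e-01
d: 1.88
e: 2.08e-07
f: 4.12e-02
g: 1.25e-02
g_i: 2.0e+07
h: 2.02e+07
j: 2.49e-02
k: 5.66e+07
K_T: 9.0e-01
K_N: 6.0e-01
K_L: 6.0e-01
K_C: 6.0e-01
l: 1.81
m: 9.12
p: 3.59e-06
p_i: 1.25e-01
q: 1.59e-06
r1: 1.1e-07
r2: 6.5e-11
s: 5.12e-01
u: 3.0e-10
alpha: 5.0e+08
alpha1: 1.0e+03
alpha2: 1.0e+03
beta: 8.0e-03
beta1: 8.35e-01
beta2: 5.4
gamma: 9.0e-01
mu1: 1.0e-01
mu_i: 10.0
delta2: 1.0e-07
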