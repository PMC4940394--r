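# Two-activator synthetic memory circuit, rational-rate-law form.
# recast_model() with aux_names c("X100", "X200") reproduces
# memory_circuit.txt.
constraint: rho1 > 1
constraint: rho2 > 1
X1. = a1*(1 + rho1*X1^2*K1^-2 + X3*K3^-1)*(1 + X1^2*K1^-2 + X3*K3^-1)^-1 - b1*X1 - k*X1*X2
X2. = a2*(1 + rho2*X2^2*K2^-2 + X3*K3^-1)*(1 + X2^2*K2^-2 + X3*K3^-1)^-1 - b2*X2 - k*X1*X2
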