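# Single-gene positive-autoregulation circuit, rational-rate-law form.
# recast_model() turns this into the GMA form in simple_circuit.txt.
constraint: rho1 > 1
X1. = a1*(1 + rho1*X1^2*K1^-2 + X3*K3^-1)*(1 + X1^2*K1^-2 + X3*K3^-1)^-1 - b1*X1 - k*X1*X2
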