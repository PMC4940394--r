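# Two-activator synthetic memory circuit, recast GMA form.
# Two autogenously activated regulators X1, X2 are coupled by irreversible
# heterodimer formation (rate k) and share a steric repressor X3.
auxiliary: X100, X200
# activation capacities are fold-changes, hence at least 1
constraint: rho1 > 1
constraint: rho2 > 1
X1. = a1*X100^-1 + a1*rho1*X1^2*K1^-2*X100^-1 + a1*X3*K3^-1*X100^-1 - b1*X1 - k*X1*X2
X2. = a2*X200^-1 + a2*rho2*X2^2*K2^-2*X200^-1 + a2*X3*K3^-1*X200^-1 - b2*X2 - k*X1*X2
0 = 1 + X1^2*K1^-2 + X3*K3^-1 - X100
0 = 1 + X2^2*K2^-2 + X3*K3^-1 - X200
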