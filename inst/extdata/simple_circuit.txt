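# Single-gene positive-autoregulation circuit, recast GMA form.
# An activator X1 drives its own synthesis (dimer binding, capacity rho1),
# is diluted by growth (b1) and sequestered into a degraded heterodimer
# with X2 (rate k); a repressor X3 competes for the control region.
auxiliary: X100
# rho1 is a fold-activation capacity, hence at least 1
constraint: rho1 > 1
X1. = a1*X100^-1 + a1*rho1*X1^2*K1^-2*X100^-1 + a1*X3*K3^-1*X100^-1 - b1*X1 - k*X1*X2
0 = 1 + X1^2*K1^-2 + X3*K3^-1 - X100
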