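# Reporter gene read-out for the memory circuit used as a counter:
# synthesis activated by X1 (capacity rho41) and repressed by X2
# (capacity rho42), first-order loss b4.
X4. = a4*(rho41*X1^2 + K1^2)*(X1^2 + K1^2)^-1*(rho42^-1*X2^2 + K2^2)*(X2^2 + K2^2)^-1 - b4*X4
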