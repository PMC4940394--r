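# Shared fixtures.  The case caches inside the package persist for the
# whole test session, so building these once keeps the suite fast.

simple_sys <- function() dsd_fixture("simple_circuit")$system

simple_pvals <- function() dsd_fixture("simple_circuit")$pvals

memory_sys <- function() dsd_fixture("memory_circuit")$system

# a small GMA system with no auxiliaries, handy for parser/stability tests
minimal_sys <- function() gma_model("X1. = a - b*X1")

# random all-positive point over the variables of a system
random_point <- function(system, log_range = 2) {
  vars <- c(system$dynamic, system$auxiliary, system$independent)
  setNames(10^runif(length(vars), -log_range, log_range), vars)
}

simple_equations <- function() {
  c("X1. = a1*X100^-1 + a1*rho1*X1^2*K1^-2*X100^-1 + a1*X3*K3^-1*X100^-1 - b1*X1 - k*X1*X2",
    "0 = 1 + X1^2*K1^-2 + X3*K3^-1 - X100")
}

simple_rational <- function() {
  "X1. = a1*(1 + rho1*X1^2*K1^-2 + X3*K3^-1)*(1 + X1^2*K1^-2 + X3*K3^-1)^-1 - b1*X1 - k*X1*X2"
}
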