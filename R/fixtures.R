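#' Packaged example circuits
#'
#' Loads one of the gene-circuit models shipped with the package:
#'
#' * `"simple_circuit"` — a single autogenously activated gene with
#'   heterodimer sequestration and a steric repressor (recast GMA form,
#'   signature (32 31), 18 possible cases).  `pvals` is a representative
#'   interior parameter set for the basal phenotype (case 1); `k = 1` by
#'   fixture convention since the heterodimerization rate constant only
#'   sets the time/concentration scale of the loss term.
#' * `"simple_circuit_rational"` — the same model in rational-rate-law
#'   form, for [recast_model()].
#' * `"memory_circuit"` — the two-activator memory circuit (signature
#'   (32 32 31 31), 324 possible cases).
#' * `"memory_circuit_rational"` — its rational form.
#' * `"memory_circuit_thresholds"` — the memory circuit rebuilt with free
#'   state-space threshold variables `Xr1`, `Xr2` as extra independent
#'   variables, for quadrant-arrangement analyses.
#' * `"counter_reporter"` — the reporter gene driven by `X1` (activation)
#'   and `X2` (repression) that turns the quadrastable memory module into
#'   a read-out counter; `pvals` holds reporter-specific defaults.
#'
#' Both circuit fixtures carry the model-level constraint that activation
#' capacities `rho*` are at least 1 (they are fold-changes relative to
#' basal expression), which the enumeration results depend on.
#'
#' @param name fixture name.
#' @return list with elements `system` (a `gma_system`, or the rational
#'   equations for `*_rational`), `pvals` (named defaults or `NULL`), and
#'   `path` (the model file).
#' @export
dsd_fixture <- function(name = c("simple_circuit", "simple_circuit_rational",
                                 "memory_circuit", "memory_circuit_rational",
                                 "memory_circuit_thresholds", "counter_reporter")) {
  name <- match.arg(name)
  file <- switch(name,
                 memory_circuit_thresholds = "memory_circuit.txt",
                 counter_reporter = "counter_reporter.txt",
                 paste0(name, ".txt"))
  path <- system.file("extdata", file, package = "dsdesign")
  if (path == "") path <- file.path("inst", "extdata", file)   # pre-install use
  pvals <- NULL
  if (name == "simple_circuit") {
    pvals <- c(K1 = 1, K3 = 10, X2 = 1, X3 = 1, a1 = 1, b1 = 10, rho1 = 10, k = 1)
  }
  if (name == "counter_reporter") {
    pvals <- c(a4 = 1, b4 = 1, rho41 = 10, rho42 = 10)
  }
  system <- switch(name,
                   simple_circuit = ,
                   memory_circuit = read_gma(path),
                   memory_circuit_thresholds = {
                     lines <- readLines(path, warn = FALSE)
                     tmp <- c(lines, "independent: Xr1, Xr2")
                     tf <- tempfile(fileext = ".txt")
                     writeLines(tmp, tf)
                     on.exit(unlink(tf))
                     read_gma(tf)
                   },
                   simple_circuit_rational = ,
                   memory_circuit_rational = ,
                   counter_reporter = read_gma(path, recast = TRUE))
  list(name = name, system = system, pvals = pvals, path = path)
}
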