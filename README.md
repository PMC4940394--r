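# dsdesign

Phenotype-centric analysis of biochemical circuit models in R.

Mechanistic models of gene circuits are non-linear ODE systems with many
unknown parameters, and analyzing them around one nominal parameter set
reveals only a sliver of what the circuit architecture can do. `dsdesign`
takes the opposite route: it deconstructs a model into a finite set of
**qualitatively distinct phenotypes** — one for every combination of
dominant production and consumption terms — characterizes each phenotype
analytically, and then *predicts* parameter values that realize phenotypes
or combinations of phenotypes of interest.

The mathematical core:

* models with rational rate laws are recast **exactly** into generalized
  mass action (GMA) form, `dX_i/dt = Σ_k α_ik Π_j X_j^g_ijk − Σ_k β_ik Π_j X_j^h_ijk`,
  plus algebraic constraints for auxiliary variables;
* keeping one dominant positive and one dominant negative term per equation
  yields an **S-system**, whose steady state is linear in log coordinates:
  `G y + a = H y + b` solves symbolically, and logarithmic gains
  `L(X_i, X_j) = ∂log X_i / ∂log X_j` are exact rational functions of the
  kinetic orders;
* the region of parameter space where that term combination actually
  dominates is a **polytope in log space**; a phenotype belongs to the
  repertoire iff its polytope is non-empty — a linear program;
* multistability, co-localization and arrangements of phenotypes are joint
  feasibility of stacked polytopes, again linear programs.

Everything downstream — repertoire enumeration, stability (eigenvalues and
Routh counts), global tolerances, ensemble prediction, design-space slices,
fixed points, basins of attraction, and ODE simulation with stimulation
events — is built on those four facts.

## Worked example

The packaged `simple_circuit` model is a single transcriptional activator
with cooperative positive autoregulation, competitive repression, dilution,
and sequestration into a degraded heterodimer:

```r
library(dsdesign)

fx  <- dsd_fixture("simple_circuit")
sys <- fx$system
valid_cases(sys)
#> [1]  1  4  7  8  9 10 11 12 15 18

phenotype_table(sys, gain_pairs = list(c("X1", "X2"), c("X1", "X3")))
#>    case_number signature L_X1_X2 L_X1_X3 positive_roots stability
#> 1            1      1111       0       0              0         S
#> 2            4      1211      -1       0              0         S
#> 3            7      2111       0       0              1         U
#> 4            8      2121       0       0              0         S
#> 5            9      2131       0       1              1         U
#> 6           10      2211       1       0              1         U
#> 7           11      2221      -1       0              0         S
#> 8           12      2231       1       1              1         U
#> 9           15      3131       0       0              0         S
#> 10          18      3231      -1       0              0         S
```

Of the 18 candidate dominance combinations, 10 are realizable somewhere in
parameter space. Case 1 is the basal phenotype (`X1 = a1/b1`, uncoupled from
both inputs); case 7 is the unstable phenotype whose coexistence with cases
1 and 8 produces a bistable switch:

```r
g <- function(k) ds_case(sys, k)
ensemble_is_valid(case_intersection(list(g(1), g(4), g(7))))   # FALSE
ensemble_is_valid(case_intersection(list(g(1), g(7), g(8))))   # TRUE
round(valid_interior_parameter_set(case_intersection(list(g(1), g(7), g(8)))), 4)
#>       a1     rho1       K1       X3       K3       b1        k       X2
#>   0.3162 100.0000   1.0000   0.1000   1.0000  10.0000   1.0000   1.0000
```

Global tolerances measure how far each parameter can move before the
phenotype changes qualitatively — here, the basal phenotype at its
reference point tolerates a 3.16-fold increase in the synthesis rate `a1`
and a 10-fold increase in the repressor `X3`, but no amount of decrease in
either:

```r
measure_tolerances(g(1), fx$pvals)
#>   parameter fold_decrease fold_increase
#> 1        a1         1e-20      3.162278
#> 2      rho1         1e-01     10.000000
#> ...
```

The two-activator `memory_circuit` scales the same analysis up: 59 valid
phenotypes of 324, of which 21 are stable and uncoupled from the repressor;
at most four can coexist (18 distinct quadrastable ensembles), and a
predicted quadrastable instance works as a three-state counter — equal
275-unit boluses of `X1` step it (−,+) → (+,+) → (+,−) and boluses of `X2`
step it back:

```r
ci   <- counter_instance()
demo <- counter_demo(ci)
demo$amount          #> 275
demo$forward_path    #> "-+" "++" "+-"
demo$backward_path   #> "+-" "++" "-+"
```

A command-line wrapper over the same functions is installed at
`inst/cli/dsdesign.R`
(`Rscript <path> enumerate --model simple_circuit --out results/`).

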