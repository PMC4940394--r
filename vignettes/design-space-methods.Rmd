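---
title: "Phenotype-centric analysis of biochemical circuits with dsdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-centric analysis of biochemical circuits with dsdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsdesign)
```

## The problem and the method

Mechanistic models of gene circuits and biochemical pathways are systems of
non-linear ODEs with many unknown parameters. The conventional workflow fixes
a nominal parameter set first and analyzes the model locally around it, which
reveals almost nothing about the repertoire of behaviors the *architecture*
can produce. `dsdesign` inverts that workflow. It deconstructs a model into a
finite set of tractable non-linear sub-systems — one per combination of
dominant production and consumption processes — treats each sub-system as a
*qualitatively distinct phenotype*, and only then asks for parameter values
that realize a phenotype (or a combination of phenotypes) of interest.

The pipeline rests on four mathematical facts:

1. **Generalized mass action (GMA) form.** Any model whose rate laws are
   power laws or rationals of power laws can be recast exactly into sums of
   products of power laws, at the cost of auxiliary variables bound by
   algebraic constraints (`recast_model()`). One auxiliary is introduced per
   distinct multi-term denominator, and the numerator is expanded through
   preserving term order — the ordering defines the case numbering, so it is
   part of the method, not a cosmetic choice.
2. **Dominant S-systems.** At any point of the (state + parameter) space,
   each equation has one largest positive and one largest negative term.
   Keeping only those terms yields an S-system whose steady state is *linear
   in logarithmic coordinates*, hence solvable symbolically
   (`solve_steady_state()`). The kinetic orders are small rationals fixed by
   mechanism, so the package does this algebra in exact rational arithmetic;
   logarithmic gains such as `L(X1, X3)` come out exact, and `0` means zero,
   not "small".
3. **Phenotypes are polytopes.** The condition that a given term combination
   actually dominates is a conjunction of linear inequalities in the logs of
   all variables (the *dominance conditions*). Substituting the S-system's
   log-linear steady state projects them onto the parameter space (the
   *boundary conditions*); a phenotype is *valid* — part of the repertoire —
   exactly when this polytope has an interior point, a linear-programming
   feasibility question (`valid_cases()`).
4. **Ensembles are stacked polytopes.** Several phenotypes coexist at one
   parameter point (multistability) iff their boundary systems are jointly
   feasible (`case_intersection()`); they co-occur within a slice of design
   space iff the stacked system with per-case replicas of the slice
   variables is feasible (`case_colocalization()`); ordering constraints
   between the replicas ($-notation) select particular arrangements.

## Numerical choices

**Linear programming.** All feasibility questions are small (tens of rows and
columns) but routinely *degenerate*: phenotype regions meet along shared
faces, and the interesting points — intersections — lie exactly there. The
package therefore ships a dense two-phase primal simplex with Bland's
smallest-index rule: it cannot cycle, it has no randomized or
condition-dependent pivoting, and every analysis is a pure function of its
inputs. Strict dominance inequalities are relaxed to `>= 0` for membership
tests and to a slack of `1e-6` log10 units for validity: LPs cannot express
strict inequalities, and a phenotype whose region is a measure-zero face is
not a phenotype anywhere in practice.

**The global box.** Every log10 variable is confined to [-20, 20]. The same
limits serve as the saturation values of the tolerance tables: a tolerance
whose 1-D bound reaches the box is reported as `1e-20`/`1e20`, i.e.
"effectively unbounded", rather than as the literal fold to the box edge.

**Interior points.** `valid_interior_parameter_set()` maximizes the minimum
row slack, capped at one log10 unit per row so that unbounded regions remain
well-posed. That optimum is almost always degenerate, so a second LP picks,
among the slack-optimal points, the one of least L1 log-distance from the
unit point (all values 1). This tie-break makes representative points
scale-balanced and reproducible; it also reproduces the character of
published representative sets for this class of circuits. Attractor counts
taken *at* such representative points (used to sub-classify multistable
ensembles into "only bistable" / "only tristable" instances) inherit this
choice and are documented as sensitive to it; the structural counts
(feasible ensembles per size, the maximum intersection size) are
rule-independent.

**Stability.** Eigenvalues are computed on the *reduced* S-system — auxiliary
variables are eliminated through the constraint block first
(`remove_algebraic_constraints()`), exactly as the steady-state algebra
requires; the Jacobian uses the analytic power-law derivatives, and
eigenvalues with `|Re| < 1e-9` relative to the spectral radius are flagged
borderline and counted as non-positive. The Routh criterion
(`routh_positive_roots()`) is kept as an independent cross-check, falling
back to eigenvalues on a zero pivot. The threshold is relative, not
absolute, because the time unit of a model is arbitrary.

**Fixed points and basins.** Candidate fixed points of the full GMA system
are the S-system steady states of all cases valid at the parameter point,
refined by a damped Newton iteration in log-state coordinates (positivity is
structural, not clamped); duplicates within `1e-6` relative log-distance
merge. Basins are resolved by integrating the full ODEs (`deSolve::lsoda`)
until a trajectory enters a `1e-3` log-neighbourhood of an attractor.

## The example circuits

Two circuits ship as plain-text models under `inst/extdata` (see
`dsd_fixture()`):

* **`simple_circuit`** — one transcriptional activator `X1` with cooperative
  (dimer) positive autoregulation (capacity `rho1`, half-saturation `K1`),
  competitive repression by `X3` (half-saturation `K3`), first-order dilution
  `b1`, and sequestration into a degraded heterodimer with a partner protein
  `X2` (rate `k`). Recast, it has system signature (32 31): 18 candidate
  phenotypes, 10 valid.
* **`memory_circuit`** — two such activators sharing the repressor and
  coupled by mutual heterodimer formation; signature (32 32 31 31), 324
  candidate phenotypes, 59 valid.

Two conventions close the gap between the circuit's biology and its bare
equations, and the enumeration results depend on them:

* `k = 1`: the heterodimerization rate constant only sets the scale of the
  loss term, so the reference parameter sets fix it at 1.
* `rho >= 1` for every activation capacity: `rho` is the fold-increase of
  synthesis at full activation, which is at least 1 by construction. Without
  this constraint the enumeration admits phenotypes that require `rho < 1`
  (repression masquerading as activation) — 14 instead of 10 for the
  single-gene circuit, 115 instead of 59 for the memory circuit.

The auto-naming scheme for auxiliary variables appends `"00"` to the
equation's variable name (`X1` → `X100`), falling back to `"01"`, `"02"`, …
when taken; explicit names can always be supplied.

## What the analyses show

For the single-gene circuit the package reproduces, from the equations
alone: the 10-phenotype repertoire with exact gain columns and stability
letters; the global-tolerance table of the basal phenotype at its
representative point; and the feasibility pattern of ensembles (cases
{1,4,7} cannot coexist, {1,7,8} can — the classic bistable triple of two
stable phenotypes plus the intervening unstable one; cases {8,12,15,18}
co-localize along the heterodimer-partner axis in some arrangements but not
in ascending order).

For the memory circuit: 21 of the 59 phenotypes are locally stable *and*
uncoupled from the repressor (both gains with respect to `X3` exactly zero);
at most 4 of them can coexist at one parameter point, in exactly 18 distinct
quadrastable ensembles; with free thresholds `Xr1`, `Xr2` partitioning the
state plane into quadrants, 24 of the 35 occupancy multisets are achievable,
and every one of the 18 ensembles can place one attractor in each quadrant.
Simulating such an instance shows counter behaviour: equal boluses of `X1`
walk the state (-,+) → (+,+) → (+,-), boluses of `X2` walk it back, and a
reporter activated by `X1` and repressed by `X2` reads the count out as
three ordered expression levels.

One caveat on reading published gain tables for the memory circuit: for
phenotypes whose `X1` balance is heterodimer-dominated
(`alpha1 = k X1 X2`), the algebra forces `L(X1, X3) = -L(X2, X3)`; the gain
of `X1` is negative when the gain of `X2` is positive. The package reports
the signed values.

## What the synthetic circuits do and do not test

The fixture circuits exercise every code path on models whose structure is
completely known, with small integer kinetic orders, explicit auxiliary
constraints, and printed reference parameter sets — so every headline number
is checkable. They do *not* probe: large systems (hundreds of LP rows),
kinetic orders with large denominators (the rational arithmetic is exact but
grows), models whose algebraic constraints are implicit (the simulator then
falls back to Newton iteration per evaluation, which is slower and can fail
far from the solution branch), or cyclical design spaces. Passing tests on
these fixtures validate the machinery, not the biology of any particular
real circuit.

## Problem sizes

All shipped analyses are desk-scale by construction: the largest enumeration
is 324 cases, the ensemble search starts from 21 phenotypes, the quadrant
analysis solves a few thousand LPs of ~13 variables, and the test-suite
grids are 7–25 points per axis (the defaults of 100 for slices and 60 for
basins suit interactive figures). These sizes were chosen to match the
printed analyses they reproduce.
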