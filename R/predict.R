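# Prediction of phenotype- and ensemble-specific parameter sets, global
# tolerances, and multistability searches.

# parse a power-law objective such as "X1^2*X2^2*X3^-2" into a log-linear
# coefficient vector over the independent variables (dependent variables are
# substituted via the case's steady-state solution)
objective_vector <- function(case, objective) {
  st <- dsd_tokenize(objective)
  st <- parse_term(st)
  term <- structured_to_powerlaw(st$value)
  vars <- all_variables(case$system)
  co <- pl_exponents(term, vars)
  dep <- c(case$system$dynamic, case$system$auxiliary)
  ci <- co[case$system$independent]
  if (length(dep)) ci <- ci + as.numeric(co[dep] %*% case$solution$gains)
  ci[ci != 0]
}

rebuild_with_constraints <- function(case, constraints) {
  if (is.null(constraints)) return(case)
  extra <- vapply(case$constraints, function(x) x$source, character(1))
  model_level <- vapply(case$system$constraints, function(x) x$source, character(1))
  ds_case(case$system, case$number,
          constraints = c(setdiff(extra, model_level), constraints))
}

#' Predict a parameter set realizing a phenotype
#'
#' Solves a linear program over the case's phenotypic polytope.  Without an
#' objective the returned point is a basic feasible vertex of the region;
#' with a power-law `objective` it is the optimum of the objective's
#' log-linear form.
#'
#' @param case a `ds_case` (or ensemble, see [case_intersection()]).
#' @param bounds optional named list of Cartesian `(min, max)` bounds.
#' @param objective optional power-law string, e.g. `"X1^2*X3^-2"`.
#' @param maximize direction for `objective`.
#' @param constraints optional extra power-law inequality strings.
#' @return named vector of positive parameter values.
#' @export
valid_parameter_set <- function(case, bounds = NULL, objective = NULL,
                                maximize = TRUE, constraints = NULL) {
  UseMethod("valid_parameter_set")
}

#' @export
valid_parameter_set.ds_case <- function(case, bounds = NULL, objective = NULL,
                                        maximize = TRUE, constraints = NULL) {
  case <- rebuild_with_constraints(case, constraints)
  if (is.null(case$boundary)) stop("case has no steady-state solution", call. = FALSE)
  obj <- if (!is.null(objective)) objective_vector(case, objective)
  res <- lp_solve(case$boundary, bounds = bounds, objective = obj, maximize = maximize)
  if (!res$feasible) {
    stop(structure(class = c("dsd_infeasible", "error", "condition"),
                   list(message = sprintf("case %d is infeasible under the given bounds/constraints",
                                          case$number), call = sys.call())))
  }
  10^res$point
}

#' Predict a parameter set in the interior of a phenotype's region
#'
#' Maximizes the minimum row slack of the boundary system (capped at one
#' log10 unit per row so unbounded regions stay well-posed), yielding a
#' point comfortably inside the phenotypic polytope.
#'
#' @inheritParams valid_parameter_set
#' @return named vector of positive parameter values.
#' @export
valid_interior_parameter_set <- function(case, bounds = NULL, constraints = NULL) {
  UseMethod("valid_interior_parameter_set")
}

#' @export
valid_interior_parameter_set.ds_case <- function(case, bounds = NULL, constraints = NULL) {
  case <- rebuild_with_constraints(case, constraints)
  if (is.null(case$boundary)) stop("case has no steady-state solution", call. = FALSE)
  res <- lp_solve(case$boundary, bounds = bounds, interior = TRUE)
  if (!res$feasible) {
    stop(structure(class = c("dsd_infeasible", "error", "condition"),
                   list(message = sprintf("case %d is infeasible under the given bounds/constraints",
                                          case$number), call = sys.call())))
  }
  10^res$point
}

#' Global tolerances of a phenotype at a reference point
#'
#' For each parameter, all other parameters are fixed and the parameter of
#' interest is pushed to the nearest boundary of the enclosing phenotypic
#' polytope in both directions (a series of 1-D linear programs, solved in
#' closed form).  Results are fold-changes relative to the reference value,
#' clipped to the global box `[1e-20, 1e20]`.
#'
#' @param case a `ds_case`.
#' @param pvals named vector of positive parameter values inside the
#'   case's region.
#' @return tibble with columns `parameter`, `fold_decrease`, `fold_increase`.
#' @export
measure_tolerances <- function(case, pvals) {
  if (is.null(case$boundary)) stop("case has no steady-state solution", call. = FALSE)
  pvals <- unlist(pvals)
  vars <- case$boundary$vars
  miss <- setdiff(vars, names(pvals))
  if (length(miss)) stop(sprintf("missing parameter '%s'", miss[1]), call. = FALSE)
  y <- log10(pvals[vars])
  if (!ineq_holds_at(case$boundary, y, tol = 1e-9)) {
    stop("reference point is outside the case's phenotypic region", call. = FALSE)
  }
  A <- case$boundary$A; b <- case$boundary$b
  rows <- lapply(seq_along(vars), function(j) {
    lb <- DSD_BOX[1]; ub <- DSD_BOX[2]
    cj <- A[, j]
    resid <- as.numeric(A %*% y + b) - cj * y[j]    # row value excluding variable j
    for (i in which(cj != 0)) {
      lim <- -resid[i] / cj[i]
      if (cj[i] > 0) lb <- max(lb, lim) else ub <- min(ub, lim)
    }
    # a bound saturating the global box means no qualitative change is
    # reachable in that direction; report the box limit itself
    tibble::tibble(parameter = vars[j],
                   fold_decrease = unname(if (lb <= DSD_BOX[1]) 10^DSD_BOX[1] else 10^(lb - y[j])),
                   fold_increase = unname(if (ub >= DSD_BOX[2]) 10^DSD_BOX[2] else 10^(ub - y[j])))
  })
  do.call(rbind, rows)
}

# --- ensembles -------------------------------------------------------------

new_ensemble <- function(kind, members, slice = character(0), constraints = NULL) {
  stopifnot(length(members) >= 1)
  sys <- members[[1]]$system
  cons <- lapply(constraints %||% character(0), parse_constraint_string)
  shared <- sys$independent
  if (length(slice)) {
    if (!all(slice %in% sys$independent)) {
      stop(sprintf("slice variable '%s' is not an independent variable",
                   setdiff(slice, sys$independent)[1]), call. = FALSE)
    }
    shared <- setdiff(shared, slice)
  }
  repl <- character(0)
  if (length(slice)) {
    repl <- as.vector(t(outer(seq_along(members) - 1L, slice,
                              function(i, v) paste0("$", v, "_", i))))
  }
  vars <- c(shared, repl)
  for (cn in cons) {
    syms <- unique(c(names(cn$lhs$en), names(cn$rhs$en)))
    bad <- setdiff(syms, vars)
    if (length(bad)) {
      stop(sprintf("ensemble constraint references unknown variable '%s'", bad[1]), call. = FALSE)
    }
  }
  structure(list(kind = kind, members = members, slice = slice,
                 constraints = cons, vars = vars, system = sys),
            class = "ds_ensemble")
}

#' Intersection of several phenotypes at a single parameter point
#'
#' Stacks the boundary conditions of all member cases over the shared
#' log-parameter space; the ensemble is valid when a single point satisfies
#' every member's conditions, i.e. the member fixed points coexist there
#' (the design-space signature of multistability).
#'
#' @param cases list of `ds_case` objects from one system.
#' @param constraints optional power-law inequality strings over the
#'   independent variables.
#' @return a `ds_ensemble`.
#' @export
case_intersection <- function(cases, constraints = NULL) {
  if (length(cases) == 0) stop("an intersection needs at least one case", call. = FALSE)
  new_ensemble("intersection", cases, constraints = constraints)
}

#' Co-localization of phenotypes within a slice of design space
#'
#' Each member case receives its own replicated copy of the slice
#' variables (named `$<variable>_<member index>`, indices starting at 0);
#' all other parameters are shared.  The ensemble is valid when all members
#' are simultaneously realized somewhere within the slice.  Constraints may
#' reference the replicated names to impose an arrangement, e.g.
#' `"$X2_0 < $X2_1"`.
#'
#' @param cases list of `ds_case` objects from one system.
#' @param slice_variables names of the independent variables spanning the
#'   slice.
#' @param constraints optional power-law inequality strings over shared
#'   parameters, slice variables, and replicated names.
#' @return a `ds_ensemble`.
#' @export
case_colocalization <- function(cases, slice_variables, constraints = NULL) {
  if (length(cases) == 0) stop("a co-localization needs at least one case", call. = FALSE)
  new_ensemble("colocalization", cases, slice = slice_variables, constraints = constraints)
}

# stacked feasibility system of an ensemble over its joint variable set
ensemble_system <- function(ens) {
  vars <- ens$vars
  member_sys <- lapply(seq_along(ens$members), function(i) {
    cs <- ens$members[[i]]
    if (is.null(cs$boundary)) return(NULL)
    iq <- cs$boundary
    if (length(ens$slice)) {
      nm <- iq$vars
      for (v in ens$slice) nm[nm == v] <- paste0("$", v, "_", i - 1L)
      iq <- ineq_system(nm, iq$A, iq$b, iq$rel)
    }
    iq
  })
  if (any(vapply(member_sys, is.null, logical(1)))) return(NULL)
  crows <- lapply(ens$constraints, constraint_row, vars = vars)
  ciq <- ineq_system(vars,
                     A = do.call(rbind, c(list(matrix(0, 0, length(vars))),
                                          lapply(crows, function(r) r$coef))),
                     b = vapply(crows, function(r) r$const, numeric(1)))
  ineq_stack(c(member_sys, list(ciq)), vars = vars)
}

#' Validity of an ensemble of phenotypes
#'
#' @param ensemble a `ds_ensemble`.
#' @param bounds optional named list of Cartesian bounds.
#' @return logical: is the stacked boundary system feasible with interior
#'   slack?
#' @export
ensemble_is_valid <- function(ensemble, bounds = NULL) {
  iq <- ensemble_system(ensemble)
  if (is.null(iq)) return(FALSE)
  lp_solve(iq, bounds = bounds, interior = TRUE)$feasible
}

#' @export
print.ds_ensemble <- function(x, ...) {
  cat(sprintf("%s of cases {%s}%s\n",
              if (x$kind == "intersection") "Case intersection" else "Case co-localization",
              paste(vapply(x$members, function(m) m$number, numeric(1)), collapse = ", "),
              if (length(x$slice)) paste0(" over slice {", paste(x$slice, collapse = ", "), "}") else ""))
  if (length(x$constraints)) {
    cat("  constraints:", paste(vapply(x$constraints, function(cc) cc$source, character(1)),
                                collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
valid_parameter_set.ds_ensemble <- function(case, bounds = NULL, objective = NULL,
                                            maximize = TRUE, constraints = NULL) {
  ensemble_parameter_set(case, interior = FALSE, bounds = bounds)
}

#' @export
valid_interior_parameter_set.ds_ensemble <- function(case, bounds = NULL, constraints = NULL) {
  ensemble_parameter_set(case, interior = TRUE, bounds = bounds)
}

#' Predict a parameter set realizing an ensemble
#'
#' @param ensemble a `ds_ensemble`.
#' @param interior if `TRUE`, maximize the minimum slack (interior point);
#'   otherwise return a vertex of the joint feasible region.
#' @param bounds optional named list of Cartesian bounds.
#' @return named vector of positive values for the shared parameters plus
#'   one entry per replicated slice variable (names `$<var>_<index>`).
#' @export
ensemble_parameter_set <- function(ensemble, interior = TRUE, bounds = NULL) {
  iq <- ensemble_system(ensemble)
  if (is.null(iq)) stop("ensemble contains a case without a steady-state solution", call. = FALSE)
  res <- lp_solve(iq, bounds = bounds, interior = interior)
  if (!res$feasible) {
    stop(structure(class = c("dsd_infeasible", "error", "condition"),
                   list(message = "ensemble is infeasible", call = sys.call())))
  }
  10^res$point
}

#' Search for all valid case intersections by pruned subset growth
#'
#' Grows candidate subsets breadth-first: a subset is only tested if its
#' sub-ensembles were feasible, justified by monotone infeasibility (adding
#' boundary rows can never make an infeasible system feasible).  The search
#' stops at the first size with no feasible intersection.
#'
#' @param system a `gma_system`.
#' @param sizes integer vector of member counts of interest.
#' @param subset case numbers to combine (e.g. the stable phenotypes of
#'   interest).
#' @param constraints optional power-law constraint strings applied to each
#'   member case.
#' @return list of `ds_ensemble` objects whose member count is in `sizes`.
#' @export
intersecting_cases <- function(system, sizes, subset, constraints = NULL) {
  sizes <- sort(unique(as.integer(sizes)))
  cases <- lapply(subset, function(k) ds_case(system, k, constraints = constraints))
  names(cases) <- as.character(subset)
  feasible_sets <- list()
  frontier <- lapply(seq_along(subset), function(i) i)
  level <- 1L
  while (length(frontier) && level < max(sizes)) {
    level <- level + 1L
    nxt <- list()
    seen <- character(0)
    for (s in frontier) {
      last <- s[length(s)]
      if (last >= length(subset)) next
      for (cnd in (last + 1L):length(subset)) {
        cand <- c(s, cnd)
        key <- paste(cand, collapse = "-")
        if (key %in% seen) next
        seen <- c(seen, key)
        ens <- case_intersection(cases[cand])
        if (ensemble_is_valid(ens)) {
          nxt[[length(nxt) + 1L]] <- cand
          if (level %in% sizes) feasible_sets[[length(feasible_sets) + 1L]] <- ens
        }
      }
    }
    frontier <- nxt
  }
  feasible_sets
}

#' Count stable and unstable fixed points at a parameter point
#'
#' Every case whose phenotypic polytope contains the point contributes one
#' fixed point of the full system; stability is read from the dominant
#' S-system's eigenvalues at that point.
#'
#' @param system a `gma_system`.
#' @param pvals named vector of positive parameter values.
#' @return list with `stable`, `unstable`, and the per-case detail tibble.
#' @export
count_attractors_at <- function(system, pvals) {
  hits <- valid_cases_at_point(system, pvals)
  detail <- lapply(hits, function(k) {
    cs <- system_cases(system)[[k]]
    pr <- tryCatch(ssys_eigenvalues(cs$ssystem, pvals)$positive_roots,
                   error = function(e) NA_integer_)
    tibble::tibble(case_number = k, positive_roots = pr)
  })
  detail <- do.call(rbind, detail) %||% tibble::tibble(case_number = integer(0),
                                                       positive_roots = integer(0))
  list(stable = sum(detail$positive_roots == 0, na.rm = TRUE),
       unstable = sum(detail$positive_roots > 0, na.rm = TRUE),
       detail = detail)
}

# --- state-space quadrant arrangements ------------------------------------

quadrant_codes <- c("--", "-+", "+-", "++")

quadrant_constraint_strings <- function(code, x_vars = c("X1", "X2"),
                                        thresholds = c("Xr1", "Xr2")) {
  signs <- strsplit(code, "")[[1]]
  vapply(seq_along(signs), function(i) {
    paste(x_vars[i], if (signs[i] == "-") "<" else ">", thresholds[i])
  }, character(1))
}

#' Test whether an ensemble admits a given quadrant arrangement
#'
#' State space is partitioned into four quadrants by free threshold
#' variables (`Xr1`, `Xr2` by default, which must be independent variables
#' of `system`).  Each member case is constrained to place its steady state
#' in its assigned quadrant, and joint feasibility is tested.
#'
#' @param system a `gma_system` whose independent variables include the
#'   thresholds.
#' @param members case numbers of the ensemble (one per quadrant slot).
#' @param quadrants character vector like `c("--", "-+", "+-", "++")`, one
#'   code per member: sign of `X1 - Xr1` then sign of `X2 - Xr2`.
#' @param x_vars,thresholds names of the state variables and thresholds.
#' @return logical.
#' @export
quadrant_arrangement_valid <- function(system, members, quadrants,
                                       x_vars = c("X1", "X2"),
                                       thresholds = c("Xr1", "Xr2")) {
  stopifnot(length(members) == length(quadrants))
  cases <- lapply(seq_along(members), function(i) {
    ds_case(system, members[i],
            constraints = quadrant_constraint_strings(quadrants[i], x_vars, thresholds))
  })
  ensemble_is_valid(case_intersection(cases))
}

#' Enumerate satisfiable quadrant-occupancy patterns
#'
#' Considers every multiset of size `n_members` over the four quadrants (35
#' patterns for ensembles of four) and reports which patterns are realized
#' by at least one of the given ensembles under some assignment of member
#' cases to quadrants.
#'
#' @param system a `gma_system` with threshold variables.
#' @param ensembles list of case-number vectors (e.g. from
#'   [intersecting_cases()]).
#' @param x_vars,thresholds see [quadrant_arrangement_valid()].
#' @return tibble with columns `pattern` (e.g. `"--/-+/+-/++"`) and
#'   `satisfiable`.
#' @export
quadrant_occupancy <- function(system, ensembles,
                               x_vars = c("X1", "X2"),
                               thresholds = c("Xr1", "Xr2")) {
  n <- length(ensembles[[1]])
  tuples <- as.matrix(expand.grid(rep(list(quadrant_codes), n),
                                  stringsAsFactors = FALSE))
  keys <- apply(tuples, 1, function(r) paste(sort(r), collapse = "/"))
  patterns <- sort(unique(keys))

  # prune: a case that cannot occupy a quadrant alone never can in company
  single_ok <- new.env(parent = emptyenv())
  can_sit <- function(case_number, code) {
    key <- paste(case_number, code)
    if (is.null(single_ok[[key]])) {
      cs <- ds_case(system, case_number,
                    constraints = quadrant_constraint_strings(code, x_vars, thresholds))
      single_ok[[key]] <- case_is_valid(cs)
    }
    single_ok[[key]]
  }

  sat <- logical(length(patterns))
  names(sat) <- patterns
  for (p in seq_along(patterns)) {
    idx <- which(keys == patterns[p])
    found <- FALSE
    for (ens in ensembles) {
      for (ti in idx) {
        codes <- tuples[ti, ]
        if (!all(vapply(seq_len(n), function(i) can_sit(ens[i], codes[i]), logical(1)))) next
        if (quadrant_arrangement_valid(system, ens, codes, x_vars, thresholds)) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    sat[p] <- found
  }
  tibble::tibble(pattern = patterns, satisfiable = unname(sat))
}
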