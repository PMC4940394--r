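# Enumeration of the phenotypic repertoire.

#' Enumerate all cases and their validity
#'
#' Builds every case of the system (the mixed-radix enumeration of dominant
#' term combinations) and tests each boundary polytope for linear-programming
#' feasibility within the global log10 box.
#'
#' @param system a `gma_system`.
#' @param constraints optional power-law inequality strings applied to every
#'   case.
#' @param bounds optional named list of Cartesian bounds per variable.
#' @return a tibble with columns `case_number`, `signature`,
#'   `has_solution` and `valid`.
#' @export
repertoire <- function(system, constraints = NULL, bounds = NULL) {
  cases <- if (is.null(constraints)) system_cases(system) else {
    lapply(seq_len(prod(case_radices(system))), function(k) {
      ds_case(system, k, constraints = constraints)
    })
  }
  rows <- lapply(cases, function(cs) {
    tibble::tibble(case_number = cs$number,
                   signature = cs$signature_string,
                   has_solution = cs$solution$exists,
                   valid = case_is_valid(cs, bounds = bounds))
  })
  do.call(rbind, rows)
}

#' Valid cases of a system
#'
#' @inheritParams repertoire
#' @return sorted integer vector of valid case numbers.
#' @export
valid_cases <- function(system, constraints = NULL, bounds = NULL) {
  rep <- repertoire(system, constraints = constraints, bounds = bounds)
  sort(rep$case_number[rep$valid])
}

#' Cases whose phenotypic polytope contains a given parameter point
#'
#' Used to count coexisting fixed points: each returned case contributes one
#' (stable or unstable) fixed point of the full system at this point.
#'
#' @param system a `gma_system`.
#' @param pvals named vector/list of positive values for all independent
#'   variables/parameters.
#' @param constraints optional power-law inequality strings.
#' @return integer vector of case numbers whose boundary conditions hold at
#'   the point (slack `>= 0`).
#' @export
valid_cases_at_point <- function(system, pvals, constraints = NULL) {
  pvals <- unlist(pvals)
  miss <- setdiff(system$independent, names(pvals))
  if (length(miss)) stop(sprintf("missing parameter '%s'", miss[1]), call. = FALSE)
  y <- log10(pvals[system$independent])
  cases <- if (is.null(constraints)) system_cases(system) else {
    lapply(seq_len(prod(case_radices(system))), function(k) {
      ds_case(system, k, constraints = constraints)
    })
  }
  hits <- integer(0)
  for (cs in cases) {
    if (!is.null(cs$boundary) && ineq_holds_at(cs$boundary, y)) hits <- c(hits, cs$number)
  }
  hits
}

#' Phenotype table: signatures, log gains and stability letters
#'
#' For each requested case, reports the signature, the logarithmic gains for
#' the requested (dependent, independent) pairs, and the local stability of
#' the dominant S-system evaluated at a predicted interior parameter point
#' (`"S"` for zero eigenvalues with positive real part, `"U"` otherwise).
#'
#' @param system a `gma_system`.
#' @param numbers case numbers (default: all valid cases).
#' @param gain_pairs list of `c(dependent, independent)` name pairs.
#' @return a tibble with one row per case.
#' @export
phenotype_table <- function(system, numbers = NULL,
                            gain_pairs = list()) {
  numbers <- numbers %||% valid_cases(system)
  rows <- lapply(numbers, function(k) {
    cs <- system_cases(system)[[k]]
    out <- tibble::tibble(case_number = cs$number, signature = cs$signature_string)
    for (gp in gain_pairs) {
      nm <- paste0("L_", gp[1], "_", gp[2])
      out[[nm]] <- if (cs$solution$exists) log_gain(cs$ssystem, gp[1], gp[2]) else NA_real_
    }
    stab <- NA_character_
    pr <- NA_integer_
    if (!is.null(cs$boundary)) {
      ip <- lp_solve(cs$boundary, interior = TRUE)
      if (ip$feasible) {
        rep_ <- tryCatch(ssys_eigenvalues(cs$ssystem, 10^ip$point),
                         error = function(e) NULL)
        if (!is.null(rep_)) {
          pr <- rep_$positive_roots
          stab <- if (pr == 0) "S" else "U"
        }
      }
    }
    out$positive_roots <- pr
    out$stability <- stab
    out
  })
  do.call(rbind, rows)
}
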