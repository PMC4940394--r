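# Qualitatively distinct phenotypes (cases): signature/number bijection,
# dominant S-systems, dominance and boundary polytopes.

# cache of fully built case lists, keyed by the system's serialized form
.dsd_case_cache <- new.env(parent = emptyenv())

system_key <- function(system) {
  paste(c(deparse_gma(system),
          vapply(system$constraints, function(cc) cc$source, character(1)),
          system$independent), collapse = "|")
}

# all cases of a system (no per-case constraints), built once and cached
system_cases <- function(system) {
  key <- system_key(system)
  if (is.null(.dsd_case_cache[[key]])) {
    total <- prod(case_radices(system))
    .dsd_case_cache[[key]] <- lapply(seq_len(total), function(k) ds_case(system, k))
  }
  .dsd_case_cache[[key]]
}

# mixed-radix numbering: digits (p1-1, q1-1, ..., pn-1, qn-1) with radices
# (P1, Q1, ..., Pn, Qn), the last digit varying fastest
case_radices <- function(system) as.numeric(t(system_signature(system)))

#' Case number from a case signature
#'
#' The signature `[p1 q1 ... pn qn]` lists the indices of the dominant
#' positive and negative terms per equation.  Numbers start at 1 for the
#' all-ones signature and enumerate signatures in mixed-radix order with the
#' last index varying fastest.
#'
#' @param system a `gma_system`.
#' @param signature integer vector of length `2n`, or a compact string such
#'   as `"1211"` (dash-separated when any term count exceeds 9).
#' @return integer case number.
#' @export
case_number <- function(system, signature) {
  radix <- case_radices(system)
  sig <- parse_signature(signature, radix)
  if (any(sig < 1 | sig > radix)) stop("signature index out of range", call. = FALSE)
  val <- 0
  for (i in seq_along(radix)) val <- val * radix[i] + (sig[i] - 1)
  as.integer(val + 1)
}

#' Case signature from a case number
#'
#' @param system a `gma_system`.
#' @param number integer case number in `1..prod(P_i * Q_i)`.
#' @param as_string return the rendered signature instead of an integer
#'   vector.
#' @return integer vector (or string) signature.
#' @export
case_signature <- function(system, number, as_string = FALSE) {
  radix <- case_radices(system)
  total <- prod(radix)
  if (number < 1 || number > total) {
    stop(sprintf("case number must be in 1..%d", total), call. = FALSE)
  }
  val <- number - 1
  sig <- integer(length(radix))
  for (i in rev(seq_along(radix))) {
    sig[i] <- val %% radix[i] + 1
    val <- val %/% radix[i]
  }
  if (as_string) render_signature(sig, radix) else sig
}

render_signature <- function(sig, radix) {
  if (all(radix <= 9)) paste(sig, collapse = "") else paste(sig, collapse = "-")
}

parse_signature <- function(signature, radix) {
  if (is.character(signature)) {
    sig <- if (grepl("-", signature)) {
      as.integer(strsplit(signature, "-")[[1]])
    } else {
      as.integer(strsplit(gsub("[][]", "", signature), "")[[1]])
    }
  } else {
    sig <- as.integer(signature)
  }
  if (length(sig) != length(radix)) {
    stop(sprintf("signature must have %d indices", length(radix)), call. = FALSE)
  }
  sig
}

# log-linear row of the ratio term_a / term_b over `vars`:
# coefficients are exponent differences, constant is log10 of the
# coefficient ratio; the row asserts log10(term_a / term_b) >= 0
term_ratio_row <- function(term_a, term_b, vars) {
  co <- pl_exponents(term_a, vars) - pl_exponents(term_b, vars)
  list(coef = co, const = log10(term_a$coef / term_b$coef))
}

constraint_row <- function(con, vars) {
  r <- term_ratio_row(con$lhs, con$rhs, vars)
  if (con$op == "<") {
    r$coef <- -r$coef; r$const <- -r$const
  }
  r
}

#' Construct a qualitatively distinct phenotype (case)
#'
#' Selects the signature's dominant terms to form the dominant S-system,
#' derives the dominance conditions (term-ratio inequalities in log space
#' over all variables), solves the S-system steady state, and projects the
#' dominance conditions onto the independent variables to obtain the
#' boundary conditions of the phenotypic polytope.
#'
#' @param system a `gma_system`.
#' @param id case number or signature.
#' @param constraints optional power-law inequality strings added to this
#'   case (dependent variables are substituted by the steady-state
#'   solution).
#' @return an object of class `ds_case`.
#' @export
ds_case <- function(system, id, constraints = NULL) {
  radix <- case_radices(system)
  if (is.numeric(id) && length(id) == 1 && id <= prod(radix)) {
    number <- as.integer(id)
    sig <- case_signature(system, number)
  } else {
    sig <- parse_signature(id, radix)
    number <- case_number(system, sig)
  }
  n <- length(system$equations)
  vars <- all_variables(system)
  dep <- c(system$dynamic, system$auxiliary)

  eqs <- vector("list", n)
  dom_rows <- list()
  for (i in seq_len(n)) {
    e <- system$equations[[i]]
    p_i <- sig[2 * i - 1]; q_i <- sig[2 * i]
    if (p_i > length(e$pos) || q_i > length(e$neg)) {
      stop("signature index out of range", call. = FALSE)
    }
    eqs[[i]] <- list(lhs_kind = e$lhs_kind, lhs = e$lhs,
                     pos = list(e$pos[[p_i]]), neg = list(e$neg[[q_i]]), source = NULL)
    for (k in seq_along(e$pos)) {
      if (k != p_i) dom_rows[[length(dom_rows) + 1L]] <- term_ratio_row(e$pos[[p_i]], e$pos[[k]], vars)
    }
    for (k in seq_along(e$neg)) {
      if (k != q_i) dom_rows[[length(dom_rows) + 1L]] <- term_ratio_row(e$neg[[q_i]], e$neg[[k]], vars)
    }
  }
  ssys <- new_ssystem(eqs, system$dynamic, system$auxiliary, system$independent)

  con_parsed <- c(system$constraints, lapply(constraints %||% character(0), parse_constraint_string))
  con_rows <- lapply(con_parsed, constraint_row, vars = vars)

  dominance <- ineq_system(vars,
                           A = do.call(rbind, c(list(matrix(0, 0, length(vars))),
                                                lapply(dom_rows, function(r) r$coef))),
                           b = vapply(dom_rows, function(r) r$const, numeric(1)))

  sol <- solve_steady_state(ssys)
  boundary <- NULL
  if (sol$exists) {
    all_rows <- c(dom_rows, con_rows)
    proj <- lapply(all_rows, function(r) {
      cd <- r$coef[dep]
      ci <- r$coef[system$independent]
      if (length(dep)) {
        ci <- ci + as.numeric(cd %*% sol$gains)
        const <- r$const + sum(cd * sol$intercept)
      } else const <- r$const
      list(coef = ci, const = const)
    })
    boundary <- ineq_system(system$independent,
                            A = do.call(rbind, c(list(matrix(0, 0, length(system$independent))),
                                                 lapply(proj, function(r) r$coef))),
                            b = vapply(proj, function(r) r$const, numeric(1)))
  }

  structure(list(number = number, signature = sig,
                 signature_string = render_signature(sig, radix),
                 system = system, ssystem = ssys, solution = sol,
                 dominance = dominance, boundary = boundary,
                 constraints = con_parsed),
            class = "ds_case")
}

#' @export
print.ds_case <- function(x, ...) {
  cat(sprintf("Case %d [%s]%s\n", x$number, x$signature_string,
              if (is.null(x$boundary)) " (no steady-state solution)" else ""))
  for (eq in deparse_gma(x$ssystem)) cat(" ", eq, "\n")
  if (!is.null(x$boundary)) cat(sprintf("  boundary polytope: %d rows over %d log-parameters\n",
                                        nrow(x$boundary$A), length(x$boundary$vars)))
  invisible(x)
}

#' Dominance conditions of a case
#'
#' One row per non-dominant term asserting that the dominant term of the
#' same sign is at least as large, in base-10 logarithms over all system
#' variables and parameters.
#'
#' @param case a `ds_case`.
#' @return an `ineq_system` over all `n + m` log-variables.
#' @export
dominance_conditions <- function(case) case$dominance

#' Boundary conditions of a case
#'
#' Dominance conditions with the dependent variables replaced by the
#' S-system's log-linear steady-state solution; rows reference only the
#' independent variables, and define the phenotypic polytope.
#'
#' @param case a `ds_case`.
#' @return an `ineq_system` over the log-parameters, or `NULL` when the
#'   S-system has no steady-state solution.
#' @export
boundary_conditions <- function(case) case$boundary

#' Test whether a case is a valid qualitatively distinct phenotype
#'
#' A case is valid when its boundary polytope (intersected with any extra
#' constraints and bounds, inside the global log10 box `[-20, 20]`) has an
#' interior point with slack at least `1e-6` log10 units.  Cases without a
#' steady-state solution have no phenotypic polytope and are invalid.
#'
#' @param case a `ds_case`.
#' @param bounds optional named list of Cartesian `(min, max)` bounds per
#'   variable.
#' @return logical.
#' @export
case_is_valid <- function(case, bounds = NULL) {
  if (is.null(case$boundary)) return(FALSE)
  lp_solve(case$boundary, bounds = bounds, interior = TRUE)$feasible
}
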