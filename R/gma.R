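#' Parse a GMA model from equation strings
#'
#' Builds a generalized mass action (GMA) system from plain-text equations.
#' Each dynamic variable owns one derivative equation (`"X1. = ..."`) and
#' each auxiliary variable owns one algebraic constraint (`"0 = ..."`).
#' Every right-hand side must be a sum of products of power laws with at
#' least one positive and one negative term.  All symbols that are not
#' dependent variables are treated as independent variables/parameters;
#' mathematically the two are interchangeable.
#'
#' @param equations character vector of equation strings.
#' @param auxiliaries character vector of auxiliary (algebraically
#'   constrained) variable names; each must appear in exactly one
#'   constraint equation.
#' @param constraints optional character vector of model-level power-law
#'   inequalities (e.g. `"rho1 > 1"`) that every phenotype must satisfy.
#' @param extra_independent optional names of independent variables that do
#'   not occur in the equations but may be referenced by constraints (e.g.
#'   state-space threshold variables).
#' @return an object of class `gma_system`.
#' @export
#' @examples
#' sys <- gma_model(c("X1. = a - b*X1"))
#' system_signature(sys)
gma_model <- function(equations, auxiliaries = character(0),
                      constraints = NULL, extra_independent = NULL) {
  parsed <- lapply(equations, parse_equation_string)
  eqs <- lapply(parsed, function(pe) {
    pos <- list(); neg <- list()
    for (t in pe$terms) {
      pl <- structured_to_powerlaw(t$factors, where = sprintf(" in \"%s\"", pe$source))
      if (pl$coef <= 0) stop("rate-constant coefficients must be positive", call. = FALSE)
      if (t$sign > 0) pos[[length(pos) + 1L]] <- pl else neg[[length(neg) + 1L]] <- pl
    }
    if (length(pos) < 1 || length(neg) < 1) {
      stop(sprintf("structural error: equation \"%s\" needs at least one positive and one negative term",
                   pe$source), call. = FALSE)
    }
    list(lhs_kind = pe$lhs_kind, lhs = pe$lhs, pos = pos, neg = neg, source = pe$source)
  })

  is_ode <- vapply(eqs, function(e) e$lhs_kind == "ode", logical(1))
  dynamic <- vapply(eqs[is_ode], function(e) e$lhs, character(1))
  cons_eqs <- eqs[!is_ode]
  if (anyDuplicated(dynamic)) stop("structural error: duplicate derivative equation", call. = FALSE)
  if (length(cons_eqs) != length(auxiliaries)) {
    stop(sprintf("structural error: %d auxiliary names declared but %d constraint equations found",
                 length(auxiliaries), length(cons_eqs)), call. = FALSE)
  }
  # match each declared auxiliary to the constraint equation that contains it
  if (length(auxiliaries)) {
    owner <- rep(NA_integer_, length(auxiliaries))
    for (i in seq_along(cons_eqs)) {
      syms <- unique(unlist(lapply(c(cons_eqs[[i]]$pos, cons_eqs[[i]]$neg), function(t) names(t$en))))
      hit <- which(auxiliaries %in% syms & is.na(owner))
      hit <- hit[auxiliaries[hit] %in% syms]
      if (length(hit) == 0) {
        stop("structural error: constraint equation does not mention an unassigned auxiliary variable",
             call. = FALSE)
      }
      owner[hit[1]] <- i
    }
    if (anyNA(owner)) {
      stop(sprintf("structural error: auxiliary '%s' has no constraint equation",
                   auxiliaries[which(is.na(owner))[1]]), call. = FALSE)
    }
    cons_eqs <- cons_eqs[owner]
  }
  eqs <- c(eqs[is_ode], cons_eqs)

  all_syms <- unique(unlist(lapply(eqs, function(e) {
    unlist(lapply(c(e$pos, e$neg), function(t) names(t$en)))
  })))
  dependent <- c(dynamic, auxiliaries)
  missing_dep <- setdiff(dependent, all_syms)
  if (length(missing_dep)) {
    stop(sprintf("structural error: dependent variable '%s' never appears in the equations",
                 missing_dep[1]), call. = FALSE)
  }
  independent <- c(setdiff(all_syms, dependent), setdiff(extra_independent %||% character(0), all_syms))

  cons <- lapply(constraints %||% character(0), parse_constraint_string)
  for (cn in cons) {
    syms <- unique(c(names(cn$lhs$en), names(cn$rhs$en)))
    unknown <- setdiff(syms, c(dependent, independent))
    independent <- c(independent, unknown)
  }

  structure(list(
    equations = eqs,
    dynamic = dynamic,
    auxiliary = as.character(auxiliaries),
    independent = independent,
    constraints = cons
  ), class = "gma_system")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.gma_system <- function(x, ...) {
  sig <- system_signature(x)
  cat(sprintf("GMA system: %d dynamic + %d auxiliary variables, %d independent variables/parameters\n",
              length(x$dynamic), length(x$auxiliary), length(x$independent)))
  cat("System signature: (", paste(t(sig), collapse = " "), ")\n", sep = "")
  for (eq in deparse_gma(x)) cat(" ", eq, "\n")
  if (length(x$constraints)) {
    cat("Constraints:", paste(vapply(x$constraints, function(cc) cc$source, character(1)),
                              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Numbers of positive and negative terms per equation
#'
#' @param system a `gma_system`.
#' @return integer matrix with one row per equation and columns `P` and `Q`.
#' @export
system_signature <- function(system) {
  stopifnot(inherits(system, "gma_system"))
  cbind(P = vapply(system$equations, function(e) length(e$pos), numeric(1)),
        Q = vapply(system$equations, function(e) length(e$neg), numeric(1)))
}

all_variables <- function(system) c(system$dynamic, system$auxiliary, system$independent)

#' Evaluate the term sums of a GMA system at a point
#'
#' @param system a `gma_system`.
#' @param point named vector of strictly positive values for every variable
#'   and parameter of the system.
#' @return a tibble with per-equation positive-term sum, negative-term sum
#'   and net rate.
#' @export
evaluate_gma <- function(system, point) {
  stopifnot(inherits(system, "gma_system"))
  point <- unlist(point)
  need <- all_variables(system)
  miss <- setdiff(need, names(point))
  if (length(miss)) stop(sprintf("missing value for '%s'", miss[1]), call. = FALSE)
  bad <- names(point)[!is.finite(point) | point <= 0]
  if (length(bad)) stop(sprintf("value for '%s' must be strictly positive", bad[1]), call. = FALSE)
  pos <- vapply(system$equations, function(e) sum(vapply(e$pos, pl_value, numeric(1), point)), numeric(1))
  neg <- vapply(system$equations, function(e) sum(vapply(e$neg, pl_value, numeric(1), point)), numeric(1))
  tibble::tibble(
    equation = seq_along(system$equations),
    lhs = vapply(system$equations, function(e) if (e$lhs_kind == "ode") e$lhs else "0", character(1)),
    positive = pos, negative = neg, net = pos - neg
  )
}

#' Serialize a GMA system back to equation strings
#'
#' @param system a `gma_system`.
#' @return character vector of equations in the input dialect.
#' @export
deparse_gma <- function(system) {
  vapply(system$equations, function(e) {
    lhs <- if (e$lhs_kind == "ode") paste0(e$lhs, ". = ") else "0 = "
    rhs <- paste(vapply(e$pos, pl_to_string, character(1)), collapse = " + ")
    for (t in e$neg) rhs <- paste0(rhs, " - ", pl_to_string(t))
    paste0(lhs, rhs)
  }, character(1))
}

#' Read a GMA or rational model from a text file
#'
#' The format is one equation per line; `#` begins a comment.  Header
#' directives `auxiliary: X100, X200`, `constraint: rho1 > 1` and
#' `independent: Xr1, Xr2` declare auxiliary variables, model-level
#' power-law constraints, and extra independent variables.
#'
#' @param path file path.
#' @param recast if `TRUE`, rational-form equations are recast into GMA
#'   form automatically.
#' @return a `gma_system`.
#' @export
read_gma <- function(path, recast = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  grab <- function(key) {
    hits <- grep(paste0("^", key, "\\s*:"), lines, value = TRUE)
    out <- unlist(lapply(hits, function(h) {
      trimws(strsplit(sub(paste0("^", key, "\\s*:"), "", h), ",")[[1]])
    }))
    out[nzchar(out)]
  }
  aux <- grab("auxiliary")
  cons <- grab("constraint")
  indep <- grab("independent")
  eqs <- lines[!grepl("^(auxiliary|constraint|independent)\\s*:", lines)]
  if (length(eqs) == 0) stop("model file contains no equations", call. = FALSE)
  if (recast) {
    recast_model(eqs, aux_names = aux, constraints = cons, extra_independent = indep)
  } else {
    gma_model(eqs, auxiliaries = aux, constraints = cons, extra_independent = indep)
  }
}
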