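#' Recast a rational-rate-law model into GMA form
#'
#' Implements the five-step recasting procedure for models whose rate terms
#' are power laws or power laws divided by sums of power laws: (1) expand
#' numerator sums by multiplying through, (2) define one auxiliary variable
#' per distinct multi-term denominator, (3) move each denominator into an
#' algebraic constraint with zero left-hand side, (4) substitute the
#' auxiliary variable for its denominator, and (5) assemble the
#' differential-algebraic GMA system.
#'
#' In the text dialect a denominator is a parenthesised sum raised to a
#' negative integer power, e.g.
#' `"X1. = a1*(1 + rho1*X1^2*K1^-2)*(1 + X1^2*K1^-2)^-1 - b1*X1"`.
#' Numerator sums (positive unit power) are expanded preserving their
#' left-to-right term order, which fixes the term numbering used by the
#' phenotype (case) machinery.
#'
#' Auxiliary variables are auto-named by suffixing the equation's variable
#' name with `"00"`; if that name is taken, `"01"`, `"02"`, ... are tried.
#' Explicit names can be supplied via `aux_names`, assigned to distinct
#' denominators in order of first appearance.
#'
#' @param equations character vector of derivative-equation strings in
#'   rational form (algebraic constraints are not allowed as input).
#' @param aux_names optional names for the auxiliary variables.
#' @param constraints,extra_independent passed on to [gma_model()].
#' @return a `gma_system`.
#' @export
recast_model <- function(equations, aux_names = NULL, constraints = NULL,
                         extra_independent = NULL) {
  parsed <- lapply(equations, parse_equation_string)
  if (any(vapply(parsed, function(p) p$lhs_kind != "ode", logical(1)))) {
    stop("rational models must consist of derivative equations only", call. = FALSE)
  }

  denominators <- list()   # canonical key -> list(terms, name)
  used_names <- unlist(lapply(parsed, function(p) {
    unlist(lapply(p$terms, function(t) {
      unlist(lapply(t$factors, function(f) if (f$kind == "sym") f$value))
    }))
  }))
  used_names <- unique(c(used_names, unlist(aux_names)))
  n_named <- 0L

  denom_key <- function(terms) {
    paste(sort(vapply(terms, pl_to_string, character(1))), collapse = " + ")
  }
  fresh_name <- function(base) {
    cand <- paste0(base, "00")
    k <- 0L
    while (cand %in% used_names) {
      k <- k + 1L
      cand <- paste0(base, sprintf("%02d", k))
    }
    cand
  }

  # expand one structured term into a list of power-law terms (numerator
  # expansion) each carrying the auxiliary factors for its denominators
  expand_term <- function(factors, eq_var) {
    base <- list(pl_new())   # running list of expanded power-law terms
    for (f in factors) {
      if (f$kind != "sum") {
        pl <- structured_to_powerlaw(list(f))
        base <- lapply(base, pl_mul, b = pl)
        next
      }
      e_num <- f$expo[["num"]]; e_den <- f$expo[["den"]]
      if (e_den != 1 || e_num != round(e_num)) {
        stop("unsupported form: parenthesised sum with non-integer exponent", call. = FALSE)
      }
      sum_terms <- lapply(f$value, function(t) {
        if (t$sign < 0) stop("unsupported form: denominator/numerator sums must have positive terms",
                             call. = FALSE)
        structured_to_powerlaw(t$factors)
      })
      if (e_num >= 1) {
        # numerator sum: multiply through, preserving term order
        for (rep in seq_len(e_num)) {
          base <- unlist(lapply(base, function(b) {
            lapply(sum_terms, function(s) pl_mul(b, s))
          }), recursive = FALSE)
        }
      } else if (e_num <= -1) {
        key <- denom_key(sum_terms)
        if (is.null(denominators[[key]])) {
          if (n_named < length(aux_names)) {
            n_named <<- n_named + 1L
            nm <- aux_names[[n_named]]
          } else {
            nm <- fresh_name(eq_var)
          }
          used_names <<- c(used_names, nm)
          denominators[[key]] <<- list(terms = sum_terms, name = nm)
        }
        nm <- denominators[[key]]$name
        base <- lapply(base, pl_mul_sym, sym = nm, expo = c(num = e_num, den = 1))
      } else {
        stop("unsupported form: parenthesised sum raised to the power zero", call. = FALSE)
      }
    }
    base
  }

  new_eqs <- character(0)
  for (p in parsed) {
    pos <- list(); neg <- list()
    for (t in p$terms) {
      expanded <- expand_term(t$factors, p$lhs)
      if (t$sign > 0) pos <- c(pos, expanded) else neg <- c(neg, expanded)
    }
    rhs <- paste(vapply(pos, pl_to_string, character(1)), collapse = " + ")
    for (tt in neg) rhs <- paste0(rhs, " - ", pl_to_string(tt))
    new_eqs <- c(new_eqs, paste0(p$lhs, ". = ", rhs))
  }
  aux <- character(0)
  for (d in denominators) {
    rhs <- paste(vapply(d$terms, pl_to_string, character(1)), collapse = " + ")
    new_eqs <- c(new_eqs, paste0("0 = ", rhs, " - ", d$name))
    aux <- c(aux, d$name)
  }
  gma_model(new_eqs, auxiliaries = aux, constraints = constraints,
            extra_independent = extra_independent)
}
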