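# Dominant S-systems: log-linear steady states, constraint elimination,
# logarithmic gains, and local stability.

# Build an S-system object (one positive and one negative power-law term per
# equation) sharing the gma_system representation, so evaluation and
# serialization reuse the GMA machinery.
new_ssystem <- function(equations, dynamic, auxiliary, independent) {
  structure(list(equations = equations, dynamic = dynamic, auxiliary = auxiliary,
                 independent = independent, constraints = list()),
            class = c("ssystem", "gma_system"))
}

#' @export
print.ssystem <- function(x, ...) {
  cat("Dominant S-system\n")
  for (eq in deparse_gma(x)) cat(" ", eq, "\n")
  invisible(x)
}

# rational kinetic-order matrices of the selected terms; columns follow
# c(dynamic, auxiliary, independent)
ssys_matrices <- function(ssys) {
  vars <- all_variables(ssys)
  n <- length(ssys$equations)
  G <- rat_mat(matrix(0, n, length(vars)))
  H <- rat_mat(matrix(0, n, length(vars)))
  a <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    tp <- ssys$equations[[i]]$pos[[1]]
    tn <- ssys$equations[[i]]$neg[[1]]
    for (s in names(tp$en)) {
      j <- match(s, vars)
      G$num[i, j] <- tp$en[[s]]; G$den[i, j] <- tp$ed[[s]]
    }
    for (s in names(tn$en)) {
      j <- match(s, vars)
      H$num[i, j] <- tn$en[[s]]; H$den[i, j] <- tn$ed[[s]]
    }
    a[i] <- log10(tp$coef); b[i] <- log10(tn$coef)
  }
  list(G = G, H = H, a = a, b = b, vars = vars)
}

rat_sub <- function(a, b) rat_elt_add(a, rat_neg(b))

#' Solve the steady state of a dominant S-system in log space
#'
#' The steady-state condition `G y + a = H y + b` is linear in the base-10
#' logarithms `y`.  The dependent block of `A = G - H` is inverted in exact
#' rational arithmetic; the solution maps each dependent log-variable to an
#' affine form in the independent log-variables, whose coefficients are the
#' logarithmic gains.
#'
#' @param ssystem an `ssystem` (see [ds_case()]).
#' @return a list with `exists`, the gain matrix `gains` (dependent rows,
#'   independent columns), intercepts `intercept` (log10), and the solution
#'   rendered as strings in `strings`.
#' @export
solve_steady_state <- function(ssystem) {
  m <- ssys_matrices(ssystem)
  dep <- c(ssystem$dynamic, ssystem$auxiliary)
  n <- length(dep)
  idx_dep <- seq_len(n)
  idx_ind <- n + seq_along(ssystem$independent)
  A <- rat_sub(m$G, m$H)
  A_dep <- rat_index(A, idx_dep, idx_dep)
  A_ind <- rat_index(A, idx_dep, idx_ind)
  Wneg <- rat_solve(A_dep, A_ind)        # A_dep^{-1} A_ind, exact
  if (is.null(Wneg)) {
    return(structure(list(exists = FALSE), class = "ssystem_solution"))
  }
  W <- rat_neg(Wneg)
  B <- m$b - m$a
  v <- as.numeric(solve(rat_as_numeric(A_dep), B))
  gains <- rat_as_numeric(W)
  dimnames(gains) <- list(dep, ssystem$independent)
  names(v) <- dep
  strings <- vapply(seq_len(n), function(i) {
    t <- pl_new(coef = 10^v[i])
    for (j in seq_along(ssystem$independent)) {
      if (W$num[i, j] != 0) {
        t <- pl_mul_sym(t, ssystem$independent[j],
                        c(num = W$num[i, j], den = W$den[i, j]))
      }
    }
    paste0(dep[i], " = ", pl_to_string(t))
  }, character(1))
  structure(list(exists = TRUE, gains = gains, gains_rational = W,
                 intercept = v, dependent = dep,
                 independent = ssystem$independent, strings = strings),
            class = "ssystem_solution")
}

#' @export
print.ssystem_solution <- function(x, ...) {
  if (!x$exists) cat("S-system steady state: none (singular dependent block)\n")
  else cat("S-system steady state:\n ", paste(x$strings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Logarithmic gain of a dependent variable with respect to an independent one
#'
#' Gains are architectural: exact rational functions of the kinetic orders,
#' independent of parameter values.
#'
#' @param ssystem an `ssystem`.
#' @param dependent,independent variable names.
#' @return the gain as a numeric value computed by exact rational arithmetic.
#' @export
log_gain <- function(ssystem, dependent, independent) {
  sol <- solve_steady_state(ssystem)
  if (!sol$exists) stop("S-system has no steady-state solution", call. = FALSE)
  if (!dependent %in% sol$dependent) stop(sprintf("unknown dependent variable '%s'", dependent), call. = FALSE)
  if (!independent %in% sol$independent) stop(sprintf("unknown independent variable '%s'", independent), call. = FALSE)
  unname(sol$gains[dependent, independent])
}

#' Eliminate algebraic constraints from a dominant S-system
#'
#' Solves the auxiliary-variable constraint block in log space and
#' substitutes the solution into the dynamic equations, producing a purely
#' dynamical S-system over the dynamic variables whose steady state and
#' gains agree with the parent's.
#'
#' @param ssystem an `ssystem`.
#' @return an `ssystem` without auxiliary variables.
#' @export
remove_algebraic_constraints <- function(ssystem) {
  n_t <- length(ssystem$dynamic)
  n_c <- length(ssystem$auxiliary)
  if (n_c == 0) return(ssystem)
  m <- ssys_matrices(ssystem)
  idx_t <- seq_len(n_t)
  idx_c <- n_t + seq_len(n_c)
  idx_i <- n_t + n_c + seq_along(ssystem$independent)
  A <- rat_sub(m$G, m$H)
  crows <- idx_c                    # constraint equations follow the dynamic ones
  A_cc <- rat_index(A, crows, idx_c)
  RS <- rat_solve(A_cc, rat_index(A, crows, c(idx_t, idx_i)))
  if (is.null(RS)) {
    stop(structure(class = c("dsd_no_reduction", "error", "condition"),
                   list(message = "auxiliary block is singular; constraints cannot be eliminated",
                        call = sys.call())))
  }
  Bc <- (m$b - m$a)[crows]
  U <- as.numeric(solve(rat_as_numeric(A_cc), Bc))
  # y_c = -R y_t - S y_I + U with [R S] = A_cc^{-1} [A_ct A_cI]
  sub_term <- function(term) {
    g <- rat_mat(matrix(0, 1, n_c))
    for (k in seq_len(n_c)) {
      s <- ssystem$auxiliary[k]
      if (s %in% names(term$en)) {
        g$num[1, k] <- term$en[[s]]; g$den[1, k] <- term$ed[[s]]
      }
    }
    if (all(g$num == 0)) return(term)
    shift <- rat_matmul(g, RS)      # 1 x (n_t + m)
    out <- pl_new(coef = term$coef * 10^sum(rat_as_numeric(g) * U))
    others <- c(ssystem$dynamic, ssystem$independent)
    for (s in names(term$en)) {
      if (s %in% ssystem$auxiliary) next
      out <- pl_mul_sym(out, s, c(num = unname(term$en[[s]]), den = unname(term$ed[[s]])))
    }
    for (j in seq_along(others)) {
      if (shift$num[1, j] != 0) {
        out <- pl_mul_sym(out, others[j], c(num = -shift$num[1, j], den = shift$den[1, j]))
      }
    }
    out
  }
  eqs <- lapply(ssystem$equations[idx_t], function(e) {
    list(lhs_kind = "ode", lhs = e$lhs,
         pos = list(sub_term(e$pos[[1]])), neg = list(sub_term(e$neg[[1]])),
         source = NULL)
  })
  new_ssystem(eqs, ssystem$dynamic, character(0), ssystem$independent)
}

#' Local stability of a purely dynamical S-system
#'
#' Evaluates the steady state at the given parameter point, forms the
#' Jacobian of the two power-law terms analytically, and reports the
#' eigenvalues.  Algebraic constraints are eliminated first if present.
#' Eigenvalues whose real part is within `1e-9` of zero relative to the
#' spectral radius are flagged borderline and counted as non-positive.
#'
#' @param ssystem an `ssystem`.
#' @param pvals named vector/list of positive values for every independent
#'   variable.
#' @return a `stability_report`: eigenvalues, `positive_roots`, `margin`,
#'   `borderline`, and the steady state used.
#' @export
ssys_eigenvalues <- function(ssystem, pvals) {
  red <- remove_algebraic_constraints(ssystem)
  sol <- solve_steady_state(red)
  if (!sol$exists) {
    stop(structure(class = c("dsd_no_solution", "error", "condition"),
                   list(message = "S-system has no steady-state solution", call = sys.call())))
  }
  pvals <- unlist(pvals)
  miss <- setdiff(red$independent, names(pvals))
  if (length(miss)) stop(sprintf("missing parameter '%s'", miss[1]), call. = FALSE)
  y_i <- log10(pvals[red$independent])
  y_t <- as.numeric(sol$gains %*% y_i) + sol$intercept
  names(y_t) <- red$dynamic
  state <- 10^y_t
  point <- c(state, pvals[red$independent])
  n_t <- length(red$dynamic)
  J <- matrix(0, n_t, n_t, dimnames = list(red$dynamic, red$dynamic))
  for (i in seq_len(n_t)) {
    flux <- pl_value(red$equations[[i]]$pos[[1]], point)
    for (j in seq_len(n_t)) {
      g <- pl_exponent(red$equations[[i]]$pos[[1]], red$dynamic[j])
      h <- pl_exponent(red$equations[[i]]$neg[[1]], red$dynamic[j])
      J[i, j] <- flux * (g - h) / state[j]
    }
  }
  ev <- eigen(J, only.values = TRUE)$values
  rad <- max(Mod(ev), 1e-300)
  tol <- 1e-9 * rad   # relative: the system's time scale is arbitrary
  structure(list(eigenvalues = ev,
                 positive_roots = sum(Re(ev) > tol),
                 margin = min(abs(Re(ev))),
                 borderline = any(abs(Re(ev)) < tol),
                 steady_state = state, jacobian = J),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability: %d eigenvalue(s) with positive real part%s\n",
              x$positive_roots, if (x$borderline) " [borderline]" else ""))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# characteristic polynomial coefficients of a matrix (monic, descending powers)
# via the Faddeev-LeVerrier recursion
char_poly_coef <- function(J) {
  n <- nrow(J)
  coefs <- numeric(n + 1)
  coefs[1] <- 1
  M <- diag(n)
  for (k in seq_len(n)) {
    M <- J %*% M
    c_k <- -sum(diag(M)) / k
    coefs[k + 1] <- c_k
    M <- M + c_k * diag(n)
  }
  coefs
}

#' Count right-half-plane roots by the Routh criterion
#'
#' Builds the Routh array of the characteristic polynomial of the reduced
#' S-system's Jacobian and counts sign changes in its first column.  This is
#' an independent cross-check of [ssys_eigenvalues()]; on a zero pivot the
#' eigenvalue count is returned with attribute `method = "eigenvalues"`.
#'
#' @inheritParams ssys_eigenvalues
#' @return integer count of roots with positive real part.
#' @export
routh_positive_roots <- function(ssystem, pvals) {
  rep_ <- ssys_eigenvalues(ssystem, pvals)
  coefs <- char_poly_coef(rep_$jacobian)
  n <- length(coefs) - 1
  if (n == 0) return(structure(0L, method = "routh"))
  rows <- max(2, n + 1)
  width <- ceiling((n + 1) / 2)
  tab <- matrix(0, rows, width)
  tab[1, ] <- coefs[seq(1, n + 1, by = 2)][seq_len(width)]
  odd <- coefs[seq(2, n + 1, by = 2)]
  tab[2, seq_along(odd)] <- odd
  fallback <- FALSE
  for (r in 3:(n + 1)) {
    if (n < 2) break
    piv <- tab[r - 1, 1]
    if (abs(piv) < 1e-12 * max(abs(tab[r - 1, ]), 1e-300)) { fallback <- TRUE; break }
    for (c in seq_len(width - 1)) {
      tab[r, c] <- (piv * tab[r - 2, c + 1] - tab[r - 2, 1] * tab[r - 1, c + 1]) / piv
    }
  }
  if (fallback) {
    return(structure(rep_$positive_roots, method = "eigenvalues"))
  }
  col1 <- tab[seq_len(n + 1), 1]
  signs <- sign(col1[col1 != 0])
  structure(sum(diff(signs) != 0), method = "routh")
}
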