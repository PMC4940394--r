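# Dense two-phase primal simplex with Bland's rule.
#
# Every feasibility and optimisation question in this package is a small,
# frequently degenerate linear program (tens of variables, tens of rows).
# Degeneracy is the rule, not the exception: phenotype boundaries meet at
# measure-zero faces, and infeasibility must be detected reliably there.
# Bland's smallest-index pivoting cannot cycle, and the fixed rule makes
# every result deterministic.
#
# Solves: max/min  obj' x   subject to  M x <= d,  x >= 0.

lp_bland <- function(M, d, obj, maximize = TRUE) {
  m <- nrow(M); n <- ncol(M)
  tol <- 1e-9 * max(1, max(abs(M)), max(abs(d)))

  # equality form: rows with negative rhs are flipped to ">=" sense and get
  # a surplus column (-1) plus an artificial; others get a slack column
  neg <- d < 0
  Meq <- M
  Meq[neg, ] <- -Meq[neg, , drop = FALSE]
  deq <- abs(d)
  slack <- diag(m)
  diag(slack)[neg] <- -1
  n_art <- sum(neg)
  art <- matrix(0, m, n_art)
  if (n_art) art[cbind(which(neg), seq_len(n_art))] <- 1
  Tab <- cbind(Meq, slack, art, deq)
  N <- n + m + n_art
  basis <- integer(m)
  basis[!neg] <- n + which(!neg)
  basis[neg] <- n + m + seq_len(n_art)

  pivot <- function(Tab, r, j) {
    Tab[r, ] <- Tab[r, ] / Tab[r, j]
    for (i in seq_len(nrow(Tab))) {
      if (i != r && abs(Tab[i, j]) > 0) Tab[i, ] <- Tab[i, ] - Tab[i, j] * Tab[r, ]
    }
    Tab
  }

  run_phase <- function(Tab, basis, cost, active) {
    repeat {
      cB <- cost[basis]
      red <- cost[active] - as.numeric(crossprod(cB, Tab[, active, drop = FALSE]))
      ent_rel <- which(red < -tol)
      if (length(ent_rel) == 0) break
      j <- active[min(ent_rel)]                       # Bland: smallest index enters
      col <- Tab[, j]
      rows <- which(col > tol)
      if (length(rows) == 0) {
        return(list(Tab = Tab, basis = basis, status = "unbounded"))
      }
      ratio <- Tab[rows, N + 1] / col[rows]
      best <- rows[ratio <= min(ratio) + tol]
      r <- best[which.min(basis[best])]               # Bland: smallest basic leaves
      Tab <- pivot(Tab, r, j)
      basis[r] <- j
    }
    list(Tab = Tab, basis = basis, status = "optimal")
  }

  if (n_art) {
    cost1 <- c(rep(0, n + m), rep(1, n_art))
    ph1 <- run_phase(Tab, basis, cost1, seq_len(N))
    Tab <- ph1$Tab; basis <- ph1$basis
    if (sum(cost1[basis] * Tab[, N + 1]) > tol * max(1, m)) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    # drive any residual (zero-valued) artificials out of the basis
    for (r in which(basis > n + m)) {
      j <- which(abs(Tab[r, seq_len(n + m)]) > tol)
      if (length(j)) {
        Tab <- pivot(Tab, r, j[1])
        basis[r] <- j[1]
      }
    }
    keep <- basis <= n + m
    Tab <- Tab[keep, , drop = FALSE]
    basis <- basis[keep]
  }

  cost2 <- c(if (maximize) -obj else obj, rep(0, m), rep(0, n_art))
  ph2 <- run_phase(Tab, basis, cost2, seq_len(n + m))
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  Tab <- ph2$Tab; basis <- ph2$basis
  x <- numeric(n)
  sel <- basis <= n
  x[basis[sel]] <- Tab[sel, N + 1]
  val <- sum(obj * x)
  list(status = "optimal", x = x, value = val)
}
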