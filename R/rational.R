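# Exact rational arithmetic on small matrices.
#
# Kinetic orders are small rationals, so the log-linear steady-state algebra
# of a dominant S-system can be carried out exactly.  Rationals are stored as
# pairs of numerator/denominator matrices whose entries are integers held in
# doubles; all magnitudes stay far below 2^53 for the system sizes this
# package targets, so the arithmetic is exact.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    r <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(b > 0, b, a)
    b <- r
  }
  ifelse(a == 0, 1, a)
}

rat_reduce <- function(x) {
  g <- rat_gcd(x$num, x$den)
  s <- ifelse(x$den < 0, -1, 1)
  list(num = s * x$num / g, den = s * x$den / g)
}

rat_mat <- function(num, den = NULL) {
  num <- as.matrix(num)
  if (is.null(den)) den <- array(1, dim(num)) else den <- as.matrix(den)
  rat_reduce(list(num = num, den = den))
}

# convert a numeric matrix of decimals with short expansions to rationals
rat_from_numeric <- function(x, max_den = 1e6) {
  x <- as.matrix(x)
  den <- array(1, dim(x))
  num <- x
  bad <- abs(num - round(num)) > 1e-12
  while (any(bad)) {
    den[bad] <- den[bad] * 10
    num[bad] <- x[bad] * den[bad]
    if (any(den > max_den)) stop("exponent is not a short finite rational", call. = FALSE)
    bad <- abs(num - round(num)) > 1e-9
  }
  rat_mat(round(num), den)
}

rat_elt_mul <- function(a, b) rat_reduce(list(num = a$num * b$num, den = a$den * b$den))
rat_elt_add <- function(a, b) rat_reduce(list(num = a$num * b$den + b$num * a$den, den = a$den * b$den))
rat_neg <- function(a) list(num = -a$num, den = a$den)

rat_as_numeric <- function(a) a$num / a$den

rat_index <- function(a, i, j) list(num = a$num[i, j, drop = FALSE], den = a$den[i, j, drop = FALSE])

rat_assign <- function(a, i, j, val) {
  a$num[i, j] <- val$num
  a$den[i, j] <- val$den
  a
}

# matrix product of two rational matrices (small sizes; triple loop is fine)
rat_matmul <- function(a, b) {
  n <- nrow(a$num); p <- ncol(a$num); m <- ncol(b$num)
  out <- rat_mat(matrix(0, n, m))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- list(num = 0, den = 1)
      for (k in seq_len(p)) {
        acc <- rat_elt_add(acc, rat_elt_mul(rat_index(a, i, k), rat_index(b, k, j)))
      }
      out <- rat_assign(out, i, j, acc)
    }
  }
  out
}

# Solve A X = B exactly by Gauss-Jordan elimination; returns NULL if singular.
rat_solve <- function(a, b) {
  n <- nrow(a$num)
  stopifnot(ncol(a$num) == n, nrow(b$num) == n)
  m <- ncol(b$num)
  aug <- rat_mat(cbind(a$num, b$num), cbind(a$den, b$den))
  for (col in seq_len(n)) {
    vals <- abs(aug$num[col:n, col] / aug$den[col:n, col])
    piv <- which(vals != 0)
    if (length(piv) == 0) return(NULL)
    piv <- col - 1 + piv[which.max(vals[piv])]
    if (piv != col) {
      aug$num[c(col, piv), ] <- aug$num[c(piv, col), ]
      aug$den[c(col, piv), ] <- aug$den[c(piv, col), ]
    }
    pv <- rat_index(aug, col, seq_len(n + m))
    pd <- list(num = pv$num[1, col], den = pv$den[1, col])
    # normalise pivot row
    row <- rat_reduce(list(num = pv$num * pd$den, den = pv$den * pd$num))
    aug$num[col, ] <- row$num
    aug$den[col, ] <- row$den
    for (r in seq_len(n)) {
      if (r == col) next
      f <- list(num = aug$num[r, col], den = aug$den[r, col])
      if (f$num == 0) next
      sub <- rat_reduce(list(num = -f$num * row$num, den = f$den * row$den))
      cur <- list(num = aug$num[r, , drop = FALSE], den = aug$den[r, , drop = FALSE])
      upd <- rat_elt_add(cur, list(num = matrix(sub$num, 1), den = matrix(sub$den, 1)))
      aug$num[r, ] <- upd$num
      aug$den[r, ] <- upd$den
    }
  }
  rat_mat(aug$num[, n + seq_len(m), drop = FALSE], aug$den[, n + seq_len(m), drop = FALSE])
}
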