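# Linear programming over log-space polytopes.
#
# All feasibility questions in the design-space method reduce to linear
# programs over base-10 logarithms of positive quantities.  Rows are kept in
# the convention  A %*% y + b >= 0; variables are shifted so the global box
# becomes the positive orthant and handed to the in-package Bland-rule
# simplex (see simplex.R).

DSD_BOX <- c(-20, 20)   # default log10 box, matching saturation values 1e-20/1e20
DSD_DELTA <- 1e-6       # interior slack (log10 units) required for validity

ineq_system <- function(vars, A = NULL, b = NULL, rel = NULL) {
  if (is.null(A)) A <- matrix(0, 0, length(vars), dimnames = list(NULL, vars))
  A <- as.matrix(A)
  colnames(A) <- vars
  b <- b %||% numeric(0)
  rel <- rel %||% rep(">=", nrow(A))
  structure(list(vars = vars, A = A, b = b, rel = rel), class = "ineq_system")
}

#' @export
print.ineq_system <- function(x, ...) {
  cat(sprintf("Linear inequality system: %d rows over log10(%s)\n",
              nrow(x$A), paste(x$vars, collapse = ", ")))
  for (i in seq_len(nrow(x$A))) {
    nz <- which(x$A[i, ] != 0)
    lhs <- paste(sprintf("%+g log %s", x$A[i, nz], x$vars[nz]), collapse = " ")
    cat(sprintf("  %s %+g %s 0\n", lhs, x$b[i], x$rel[i]))
  }
  invisible(x)
}

# stack inequality systems defined over (subsets of) a common variable set
ineq_stack <- function(systems, vars = NULL) {
  vars <- vars %||% unique(unlist(lapply(systems, function(s) s$vars)))
  A <- do.call(rbind, lapply(systems, function(s) {
    m <- matrix(0, nrow(s$A), length(vars), dimnames = list(NULL, vars))
    m[, s$vars] <- s$A
    m
  }))
  b <- unlist(lapply(systems, function(s) s$b))
  rel <- unlist(lapply(systems, function(s) s$rel))
  ineq_system(vars, A, b %||% numeric(0), rel %||% character(0))
}

# Convert named Cartesian bounds (list(X3 = c(1e-3, 1e3))) into per-variable
# log10 lower/upper vectors over `vars`.  A scalar entry fixes the variable.
resolve_bounds <- function(vars, bounds = NULL, box = DSD_BOX) {
  lo <- rep(box[1], length(vars)); hi <- rep(box[2], length(vars))
  names(lo) <- names(hi) <- vars
  for (nm in names(bounds %||% list())) {
    if (!nm %in% vars) next
    v <- bounds[[nm]]
    if (any(v <= 0)) stop(sprintf("bounds for '%s' must be positive", nm), call. = FALSE)
    if (length(v) == 1) { lo[nm] <- hi[nm] <- log10(v) }
    else { lo[nm] <- log10(v[1]); hi[nm] <- log10(v[2]) }
  }
  list(lo = lo, hi = hi)
}

# Solve over the rows of `iq` intersected with the box.
#  - objective NULL + interior=FALSE: any basic feasible point (phase-1 vertex)
#  - objective (named coef vector) : optimum of the log-linear objective
#  - interior=TRUE: maximise the minimum row slack, capped at `slack_cap`
# Returns list(feasible, point (log10 scale), minslack, value, status).
lp_solve <- function(iq, bounds = NULL, box = DSD_BOX, objective = NULL,
                     maximize = TRUE, interior = FALSE, slack_cap = 1,
                     delta = DSD_DELTA) {
  vars <- iq$vars
  n <- length(vars)
  bb <- resolve_bounds(vars, bounds, box)
  lo <- bb$lo; hi <- bb$hi
  A <- iq$A; b <- iq$b
  eqr <- iq$rel == "="
  Aeq <- A[eqr, , drop = FALSE]; beq <- b[eqr]
  A <- A[!eqr, , drop = FALSE]; b <- b[!eqr]

  ncols <- n + as.integer(interior)
  # shift x = y - lo so the solver's x >= 0 matches the lower box bound;
  # ">=" rows A y + b >= (t) become "<=" rows  -A x (+ t) <= b + A lo
  Aub <- -A
  if (interior) Aub <- cbind(Aub, rep(1, nrow(Aub)))
  bub <- as.numeric(b + A %*% lo)
  Aub <- rbind(Aub, cbind(diag(n), if (interior) 0))
  bub <- c(bub, hi - lo)
  if (interior) {
    Aub <- rbind(Aub, c(rep(0, n), 1))
    bub <- c(bub, slack_cap)
  }
  if (nrow(Aeq)) {
    Aub <- rbind(Aub, cbind(-Aeq, if (interior) 0), cbind(Aeq, if (interior) 0))
    bub <- c(bub, as.numeric(beq + Aeq %*% lo), as.numeric(-beq - Aeq %*% lo))
  }
  obj <- rep(0, ncols)
  if (interior) obj[ncols] <- 1
  maxi <- TRUE
  if (!is.null(objective)) {
    ov <- rep(0, n); names(ov) <- vars
    ov[names(objective)] <- objective
    obj[seq_len(n)] <- ov
    maxi <- maximize
  }
  res <- lp_bland(Aub, bub, obj, maximize = maxi)
  if (res$status != "optimal") {
    return(list(feasible = FALSE, point = NULL, minslack = -Inf, value = NA_real_,
                status = res$status))
  }
  if (interior && res$x[ncols] > 0) {
    # stage 2: among the (typically degenerate) max-min-slack optima, pick
    # the point of least L1 log-distance from the unit point y = 0 --
    # a deterministic, scale-balanced representative of the region
    tstar <- res$x[ncols]
    ctr <- pmin(pmax(0, lo), hi) - lo
    A2s <- rbind(cbind(-A, matrix(0, nrow(A), n)),               # A y >= t* - b
                 cbind(diag(n), matrix(0, n, n)),                # x <= hi - lo
                 cbind(diag(n), -diag(n)),                       # x - z <= ctr
                 cbind(-diag(n), -diag(n)))                      # -x - z <= -ctr
    b2s <- c(as.numeric(b + A %*% lo) - tstar, hi - lo, ctr, -ctr)
    if (nrow(Aeq)) {
      A2s <- rbind(A2s, cbind(-Aeq, matrix(0, nrow(Aeq), n)),
                   cbind(Aeq, matrix(0, nrow(Aeq), n)))
      b2s <- c(b2s, as.numeric(beq + Aeq %*% lo), as.numeric(-beq - Aeq %*% lo))
    }
    res2 <- lp_bland(A2s, b2s, c(rep(0, n), rep(1, n)), maximize = FALSE)
    if (res2$status == "optimal") {
      res$x <- c(res2$x[seq_len(n)], tstar)
    }
  }
  x <- res$x[seq_len(n)]
  y <- x + lo
  names(y) <- vars
  slacks <- if (nrow(A)) as.numeric(A %*% y + b) else Inf
  minslack <- if (interior) unname(res$x[ncols]) else min(slacks)
  list(feasible = !interior || minslack >= delta,
       point = y, minslack = minslack,
       value = res$value, status = "solved")
}

# Fast membership test: does the log10 point satisfy every row (slack >= 0)?
ineq_holds_at <- function(iq, y, tol = 0) {
  if (nrow(iq$A) == 0) return(TRUE)
  y <- y[iq$vars]
  if (anyNA(y)) stop("point does not assign every variable of the inequality system", call. = FALSE)
  s <- as.numeric(iq$A %*% y + iq$b)
  ok <- ifelse(iq$rel == "=", abs(s) <= 1e-9, s >= -tol)
  all(ok)
}
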