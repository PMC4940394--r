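# Design-space slices, state-space trajectory classes, fixed points,
# simulation and basins of attraction.

log_grid <- function(range, resolution) {
  if (any(range <= 0) || range[1] >= range[2]) {
    stop("grid ranges must be positive with min < max", call. = FALSE)
  }
  10^seq(log10(range[1]), log10(range[2]), length.out = resolution)
}

#' Classify a 2-D slice of design space
#'
#' Samples a log-uniform grid over two independent variables (all other
#' parameters fixed at `pvals`) and labels each grid point with the set of
#' cases whose phenotypic polytope contains it.  Overlaps (several cases at
#' one point) mark regions with multiple fixed points.
#'
#' @param system a `gma_system`.
#' @param pvals named reference values for the non-slice parameters.
#' @param x_var,y_var names of the slice variables.
#' @param x_range,y_range Cartesian `(min, max)` ranges.
#' @param resolution grid points per axis.
#' @param intersections optional integer filter: only label points whose
#'   number of coexisting cases is in this set.
#' @return tibble with columns `x`, `y`, `n_cases`, `label` (case numbers
#'   joined by `+`, `NA` where filtered out).
#' @export
classify_slice <- function(system, pvals, x_var, y_var, x_range, y_range,
                           resolution = 100, intersections = NULL) {
  gx <- log10(log_grid(x_range, resolution))
  gy <- log10(log_grid(y_range, resolution))
  grid <- expand.grid(x = gx, y = gy)
  pvals <- unlist(pvals)
  vars <- system$independent
  base <- rep(NA_real_, length(vars)); names(base) <- vars
  fixed <- setdiff(vars, c(x_var, y_var))
  miss <- setdiff(fixed, names(pvals))
  if (length(miss)) stop(sprintf("missing parameter '%s'", miss[1]), call. = FALSE)
  base[fixed] <- log10(pvals[fixed])
  total <- prod(case_radices(system))
  labels <- vector("list", nrow(grid))
  counts <- integer(nrow(grid))
  for (k in seq_len(total)) {
    cs <- system_cases(system)[[k]]
    if (is.null(cs$boundary)) next
    A <- cs$boundary$A; b <- cs$boundary$b
    if (nrow(A) == 0) { member <- rep(TRUE, nrow(grid)) } else {
      const <- as.numeric(A[, fixed, drop = FALSE] %*% base[fixed]) + b
      vals <- outer(A[, x_var], grid$x) + outer(A[, y_var], grid$y) + const
      member <- colSums(vals < 0) == 0
    }
    counts[member] <- counts[member] + 1L
    for (i in which(member)) labels[[i]] <- c(labels[[i]], k)
  }
  lab <- vapply(labels, function(l) if (is.null(l)) "" else paste(l, collapse = "+"), character(1))
  if (!is.null(intersections)) lab[!(counts %in% intersections)] <- NA_character_
  tibble::tibble(x = 10^grid$x, y = 10^grid$y, n_cases = counts, label = lab)
}

#' Number of unstable directions across a 2-D slice
#'
#' At each grid point, sums the count of eigenvalues with positive real
#' part over all cases valid there: 0 marks monostable regions and 1 marks
#' the classic bistable overlap (two stable cases plus one unstable).
#'
#' @inheritParams classify_slice
#' @return tibble with columns `x`, `y`, `positive_roots`.
#' @export
positive_roots_slice <- function(system, pvals, x_var, y_var, x_range, y_range,
                                 resolution = 40) {
  cls <- classify_slice(system, pvals, x_var, y_var, x_range, y_range, resolution)
  pvals <- unlist(pvals)
  cache <- new.env(parent = emptyenv())
  pr <- mapply(function(lab, x, y) {
    if (is.na(lab) || lab == "") return(0L)
    pv <- pvals
    pv[x_var] <- x; pv[y_var] <- y
    sum(vapply(strsplit(lab, "+", fixed = TRUE)[[1]], function(k) {
      key <- paste(k, x, y)
      if (is.null(cache[[key]])) {
        cs <- ds_case(system, as.integer(k))
        cache[[key]] <- tryCatch(ssys_eigenvalues(cs$ssystem, pv)$positive_roots,
                                 error = function(e) 0L)
      }
      cache[[key]]
    }, integer(1)))
  }, cls$label, cls$x, cls$y)
  tibble::tibble(x = cls$x, y = cls$y, positive_roots = as.integer(pr))
}

# Solve the algebraic constraints for the auxiliary variables at a given
# state.  Fast path: each auxiliary appears only as the lone negative term
# (exponent 1) of its own constraint, and no constraint's positive terms
# reference an auxiliary -- then the constraints are explicit.  Otherwise a
# damped Newton iteration in log coordinates is used.
solve_auxiliaries <- function(system, point) {
  aux <- system$auxiliary
  if (length(aux) == 0) return(point)
  n_t <- length(system$dynamic)
  cons <- system$equations[n_t + seq_along(aux)]
  explicit <- all(vapply(seq_along(aux), function(i) {
    e <- cons[[i]]
    neg_syms <- names(e$neg[[1]]$en)
    pos_syms <- unlist(lapply(e$pos, function(t) names(t$en)))
    length(e$neg) == 1 && identical(neg_syms, aux[i]) &&
      e$neg[[1]]$en[[aux[i]]] == 1 && e$neg[[1]]$ed[[aux[i]]] == 1 &&
      !any(pos_syms %in% aux)
  }, logical(1)))
  if (explicit) {
    for (i in seq_along(aux)) {
      e <- cons[[i]]
      point[aux[i]] <- sum(vapply(e$pos, pl_value, numeric(1), point)) / e$neg[[1]]$coef
    }
    return(point)
  }
  y <- rep(0, length(aux)); names(y) <- aux
  resid <- function(y) {
    point[aux] <- 10^y
    vapply(cons, function(e) {
      sum(vapply(e$pos, pl_value, numeric(1), point)) -
        sum(vapply(e$neg, pl_value, numeric(1), point))
    }, numeric(1))
  }
  for (it in seq_len(100)) {
    f <- resid(y)
    if (max(abs(f)) < 1e-12 * max(1, max(abs(f)))) break
    J <- matrix(0, length(aux), length(aux))
    h <- 1e-6
    for (j in seq_along(aux)) {
      yp <- y; yp[j] <- yp[j] + h
      J[, j] <- (resid(yp) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    for (d in seq_len(30)) {
      fn <- resid(y + lam * step)
      if (sum(fn^2) < sum(f^2)) break
      lam <- lam / 2
    }
    y <- y + lam * step
    if (max(abs(lam * step)) < 1e-12) break
  }
  point[aux] <- 10^y
  point
}

# net right-hand sides of the dynamic equations with auxiliaries eliminated
gma_rhs <- function(system, state, pvals) {
  point <- c(state, unlist(pvals))
  point <- solve_auxiliaries(system, point)
  n_t <- length(system$dynamic)
  vapply(system$equations[seq_len(n_t)], function(e) {
    sum(vapply(e$pos, pl_value, numeric(1), point)) -
      sum(vapply(e$neg, pl_value, numeric(1), point))
  }, numeric(1))
}

#' Qualitatively distinct trajectory classes over a state-space grid
#'
#' At each grid point of the two dynamic variables, the dominant positive
#' and dominant negative term of each equation are identified numerically
#' (auxiliary variables solved from their constraints) and the per-equation
#' sign of their difference assigns one of four direction classes:
#' `"NE"`, `"NW"`, `"SE"`, `"SW"` (east = first variable increasing,
#' north = second variable increasing).
#'
#' @param system a `gma_system` with exactly two dynamic variables.
#' @param pvals named parameter values.
#' @param x_range,y_range Cartesian ranges for the two dynamic variables.
#' @param resolution grid points per axis.
#' @return tibble with columns `x`, `y`, `class`.
#' @export
trajectory_classes <- function(system, pvals, x_range, y_range, resolution = 60) {
  if (length(system$dynamic) != 2) {
    stop("trajectory classes are defined for systems with two dynamic variables", call. = FALSE)
  }
  gx <- log_grid(x_range, resolution)
  gy <- log_grid(y_range, resolution)
  grid <- expand.grid(x = gx, y = gy)
  pvals <- unlist(pvals)
  n_t <- 2L
  cls <- vapply(seq_len(nrow(grid)), function(i) {
    state <- c(grid$x[i], grid$y[i])
    names(state) <- system$dynamic
    point <- solve_auxiliaries(system, c(state, pvals))
    dir <- vapply(system$equations[seq_len(n_t)], function(e) {
      dp <- max(vapply(e$pos, pl_value, numeric(1), point))
      dn <- max(vapply(e$neg, pl_value, numeric(1), point))
      dp >= dn
    }, logical(1))
    paste0(if (dir[2]) "N" else "S", if (dir[1]) "E" else "W")
  }, character(1))
  tibble::tibble(x = grid$x, y = grid$y, class = cls)
}

#' Locate the fixed points of the full GMA system at a parameter point
#'
#' Candidates are the S-system steady states of every case valid at the
#' point; each is optionally refined against the full equations by a damped
#' Newton iteration in log-state coordinates (positivity-preserving).
#' Duplicates within relative log-distance `1e-6` are merged keeping the
#' refined one; stability is re-evaluated on the full-system Jacobian.
#'
#' @param system a `gma_system`.
#' @param pvals named parameter values.
#' @param refine refine candidates against the full equations?
#' @return tibble with one row per fixed point: the dynamic-variable
#'   values, `case_number`, `stable`, `refined`, `residual`.
#' @export
find_fixed_points <- function(system, pvals, refine = TRUE) {
  pvals <- unlist(pvals)
  hits <- valid_cases_at_point(system, pvals)
  n_t <- length(system$dynamic)
  cand <- list()
  for (k in hits) {
    cs <- system_cases(system)[[k]]
    red <- tryCatch(remove_algebraic_constraints(cs$ssystem), error = function(e) NULL)
    if (is.null(red)) next
    sol <- solve_steady_state(red)
    if (!sol$exists) next
    y <- as.numeric(sol$gains %*% log10(pvals[red$independent])) + sol$intercept
    names(y) <- red$dynamic
    cand[[length(cand) + 1L]] <- list(case = k, y = y)
  }
  rel_resid <- function(y) {
    y <- pmin(pmax(y, -30), 30)
    state <- 10^y; names(state) <- system$dynamic
    point <- solve_auxiliaries(system, c(state, pvals))
    out <- vapply(system$equations[seq_len(n_t)], function(e) {
      p <- sum(vapply(e$pos, pl_value, numeric(1), point))
      q <- sum(vapply(e$neg, pl_value, numeric(1), point))
      (p - q) / max(p, q)
    }, numeric(1))
    out[!is.finite(out)] <- 1
    out
  }
  newton <- function(y) {
    for (it in seq_len(60)) {
      f <- rel_resid(y)
      if (max(abs(f)) < 1e-12) return(list(y = y, ok = TRUE))
      J <- matrix(0, n_t, n_t)
      h <- 1e-7
      for (j in seq_len(n_t)) {
        yp <- y; yp[j] <- yp[j] + h
        J[, j] <- (rel_resid(yp) - f) / h
      }
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) return(list(y = y, ok = FALSE))
      lam <- 1
      repeat {
        fn <- rel_resid(y + lam * step)
        if ((all(is.finite(fn)) && sum(fn^2) <= sum(f^2)) || lam < 2^-30) break
        lam <- lam / 2
      }
      if (lam < 2^-30) return(list(y = y, ok = max(abs(f)) < 1e-9))
      y <- y + lam * step
    }
    list(y = y, ok = max(abs(rel_resid(y))) < 1e-9)
  }
  pts <- list()
  for (cn in cand) {
    y <- cn$y; ok <- FALSE
    if (refine) {
      r <- newton(cn$y)
      if (r$ok) { y <- r$y; ok <- TRUE }
    }
    pts[[length(pts) + 1L]] <- list(case = cn$case, y = y, refined = ok,
                                    residual = max(abs(rel_resid(y))))
  }
  # merge duplicates, preferring refined points
  keep <- list()
  for (p in pts) {
    dup <- FALSE
    for (i in seq_along(keep)) {
      if (max(abs(p$y - keep[[i]]$y)) < 1e-6) {
        dup <- TRUE
        if (p$refined && !keep[[i]]$refined) keep[[i]] <- p
        break
      }
    }
    if (!dup) keep[[length(keep) + 1L]] <- p
  }
  rows <- lapply(keep, function(p) {
    state <- 10^p$y; names(state) <- system$dynamic
    J <- matrix(0, n_t, n_t)
    h <- 1e-6
    f0 <- gma_rhs(system, state, pvals)
    for (j in seq_len(n_t)) {
      sp <- state; sp[j] <- sp[j] * (1 + h)
      J[, j] <- (gma_rhs(system, sp, pvals) - f0) / (state[j] * h)
    }
    ev <- eigen(J, only.values = TRUE)$values
    out <- tibble::as_tibble(as.list(state))
    out$case_number <- p$case
    out$stable <- all(Re(ev) < 1e-9 * max(Mod(ev), 1e-300))
    out$refined <- p$refined
    out$residual <- p$residual
    out
  })
  do.call(rbind, rows) %||%
    tibble::as_tibble(setNames(rep(list(numeric(0)), n_t + 4),
                               c(system$dynamic, "case_number", "stable", "refined", "residual")))
}

#' Simulate the full GMA system with transient stimulation events
#'
#' Integrates the dynamic equations (auxiliary variables solved from their
#' constraints at every evaluation) with a stiff-capable solver.  Boluses
#' add the stated amount to the stated variable at the stated time.
#'
#' @param system a `gma_system`.
#' @param pvals named parameter values.
#' @param initial named positive initial state for the dynamic variables.
#' @param t_end end time.
#' @param boluses optional data frame with columns `time`, `var`, `amount`.
#' @param n_out number of output time points.
#' @return tibble with `time` and one column per dynamic variable.
#' @export
simulate_gma <- function(system, pvals, initial, t_end, boluses = NULL,
                         n_out = 400) {
  pvals <- unlist(pvals)
  initial <- unlist(initial)[system$dynamic]
  if (anyNA(initial) || any(initial <= 0)) {
    stop("initial state must assign a positive value to every dynamic variable", call. = FALSE)
  }
  rhs <- function(t, y, parms) {
    names(y) <- system$dynamic
    list(gma_rhs(system, pmax(y, 1e-30), pvals))
  }
  times <- sort(unique(c(seq(0, t_end, length.out = n_out),
                         if (!is.null(boluses)) boluses$time)))
  events <- NULL
  if (!is.null(boluses) && nrow(boluses)) {
    events <- list(data = data.frame(var = boluses$var, time = boluses$time,
                                     value = boluses$amount, method = "add"))
  }
  out <- deSolve::ode(y = initial, times = times, func = rhs, parms = NULL,
                      method = "lsoda", events = events,
                      rtol = 1e-8, atol = 1e-12)
  if (attr(out, "istate")[1] < 0) {
    stop("integration failed; last state at t = ", max(out[, 1]), call. = FALSE)
  }
  tibble::as_tibble(as.data.frame(out))
}

#' Basins of attraction over a state-space grid
#'
#' Integrates the full system from each grid point until the trajectory
#' comes within relative log-distance `1e-3` of a stable fixed point or the
#' time cap is reached.
#'
#' @param system a `gma_system` with two dynamic variables.
#' @param pvals named parameter values.
#' @param x_range,y_range Cartesian grid ranges for the dynamic variables.
#' @param resolution grid points per axis.
#' @param fixed_points optional precomputed result of [find_fixed_points()].
#' @param t_cap integration time cap.
#' @return tibble with `x`, `y` and `attractor` (row index into the stable
#'   fixed points, `NA` if unresolved).
#' @export
basins <- function(system, pvals, x_range, y_range, resolution = 60,
                   fixed_points = NULL, t_cap = 500) {
  fp <- fixed_points %||% find_fixed_points(system, pvals)
  fp <- fp[fp$stable, , drop = FALSE]
  if (nrow(fp) == 0) stop("no stable fixed points at this parameter point", call. = FALSE)
  att <- log10(as.matrix(fp[, system$dynamic]))
  gx <- log_grid(x_range, resolution)
  gy <- log_grid(y_range, resolution)
  grid <- expand.grid(x = gx, y = gy)
  pvals <- unlist(pvals)
  nearest <- function(y) {
    d <- apply(att, 1, function(a) max(abs(a - y)))
    if (min(d) < 1e-3) which.min(d) else NA_integer_
  }
  rhs <- function(t, y, parms) {
    names(y) <- system$dynamic
    list(gma_rhs(system, pmax(y, 1e-30), pvals))
  }
  lab <- vapply(seq_len(nrow(grid)), function(i) {
    state <- c(grid$x[i], grid$y[i]); names(state) <- system$dynamic
    hit <- nearest(log10(state))
    t <- 0; chunk <- max(t_cap / 25, 1)
    while (is.na(hit) && t < t_cap) {
      out <- deSolve::ode(y = state, times = c(0, chunk), func = rhs, parms = NULL,
                          method = "lsoda", rtol = 1e-6, atol = 1e-10)
      state <- pmax(out[nrow(out), -1], 1e-30)
      names(state) <- system$dynamic
      t <- t + chunk
      hit <- nearest(log10(state))
    }
    hit
  }, integer(1))
  tibble::tibble(x = grid$x, y = grid$y, attractor = lab)
}
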