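# A quadrastable instance of the memory circuit wired as a stable counter:
# one attractor per state-space quadrant, a reporter read out from X1
# (activation) and X2 (repression), and transient boluses that walk the
# system through (-,+) -> (+,+) -> (+,-) and back.

#' Predict a quadrastable counter instance of the memory circuit
#'
#' Runs the whole phenotype-centric pipeline: enumerates the memory
#' circuit's repertoire, filters to stable phenotypes uncoupled from the
#' repressor, finds the size-4 stable intersections, and predicts an
#' interior parameter set for the first ensemble that places one attractor
#' in each state-space quadrant (thresholds `Xr1 = Xr2 = 1`).
#'
#' @param members optional case numbers of a quadrastable ensemble (skips
#'   the search).
#' @param quadrants optional quadrant codes for `members`.
#' @return list with `system` (the memory circuit), `pvals`, `thresholds`,
#'   `members`, `quadrants`, and the `fixed_points` tibble augmented with a
#'   `quadrant` column.
#' @export
counter_instance <- function(members = NULL, quadrants = NULL) {
  fxq <- dsd_fixture("memory_circuit_thresholds")
  sysq <- fxq$system
  fx <- dsd_fixture("memory_circuit")
  sys <- fx$system

  if (is.null(members)) {
    tb <- phenotype_table(sys, gain_pairs = list(c("X1", "X3"), c("X2", "X3")))
    crit <- tb$case_number[tb$stability == "S" & tb$L_X1_X3 == 0 & tb$L_X2_X3 == 0]
    ens4 <- intersecting_cases(sys, 4, crit)
    if (length(ens4) == 0) stop("no quadrastable ensemble found", call. = FALSE)
    members <- sort(vapply(ens4[[1]]$members, function(m) m$number, numeric(1)))
  }
  perm4 <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perm4(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  bounds <- list(Xr1 = 1, Xr2 = 1)
  assignment <- NULL
  for (q in if (is.null(quadrants)) perm4(quadrant_codes) else list(quadrants)) {
    cases <- lapply(seq_along(members), function(i) {
      ds_case(sysq, members[i], constraints = quadrant_constraint_strings(q[i]))
    })
    ens <- case_intersection(cases)
    iq <- ensemble_system(ens)
    res <- lp_solve(iq, bounds = bounds, interior = TRUE)
    if (res$feasible) { assignment <- list(q = q, point = 10^res$point); break }
  }
  if (is.null(assignment)) {
    stop("ensemble admits no one-attractor-per-quadrant arrangement with unit thresholds",
         call. = FALSE)
  }
  pvals <- assignment$point[sys$independent]
  fp <- find_fixed_points(sys, pvals)
  thr <- assignment$point[c("Xr1", "Xr2")]
  fp$quadrant <- paste0(ifelse(fp$X1 < thr[["Xr1"]], "-", "+"),
                        ifelse(fp$X2 < thr[["Xr2"]], "-", "+"))
  list(system = sys, pvals = pvals, thresholds = thr,
       members = members, quadrants = assignment$q, fixed_points = fp)
}

# quadrant of a state relative to the thresholds
state_quadrant <- function(state, thresholds) {
  paste0(ifelse(state[[1]] < thresholds[[1]], "-", "+"),
         ifelse(state[[2]] < thresholds[[2]], "-", "+"))
}

#' Drive the counter through its three-state cycle
#'
#' Starting at the `(-,+)` attractor, two equal boluses of the positive
#' channel `X1` (spaced `interval` time units apart) step the system
#' through `(+,+)` to `(+,-)`; two boluses of the negative channel `X2`
#' then walk it back.  The bolus amount is calibrated automatically: the
#' first candidate (275 concentration units, tried first) that completes
#' the forward transition chain is used.
#'
#' @param instance result of [counter_instance()].
#' @param amount optional bolus amount (skips calibration).
#' @param interval spacing between stimulations in time units.
#' @return list with `amount`, `forward` and `backward` trajectory tibbles,
#'   and the visited quadrant sequences `forward_path`, `backward_path`.
#' @export
counter_demo <- function(instance, amount = NULL, interval = 20) {
  fp <- instance$fixed_points
  stable <- fp[fp$stable, , drop = FALSE]
  start_f <- stable[stable$quadrant == "-+", , drop = FALSE]
  if (nrow(start_f) == 0) stop("no (-,+) attractor in this instance", call. = FALSE)
  sys <- instance$system
  thr <- instance$thresholds

  run <- function(start, var, amt) {
    boluses <- data.frame(time = c(interval, 2 * interval), var = var, amount = amt)
    tr <- simulate_gma(sys, instance$pvals,
                       c(X1 = start$X1, X2 = start$X2), t_end = 3 * interval,
                       boluses = boluses, n_out = 150)
    probe <- function(t) {
      i <- which.min(abs(tr$time - t))
      state_quadrant(c(tr$X1[i], tr$X2[i]), thr)
    }
    list(trajectory = tr,
         path = c(probe(interval - 1e-6), probe(2 * interval - 1e-6), probe(3 * interval)))
  }

  candidates <- if (is.null(amount)) {
    xpp <- stable$X1[stable$quadrant == "++"]
    unique(c(275, signif(c(2, 5, 10, 30, 100, 300) * max(xpp, 1), 3)))
  } else amount
  chosen <- NULL
  fwd <- NULL
  for (a in candidates) {
    f <- run(start_f[1, ], "X1", a)
    if (identical(f$path, c("-+", "++", "+-"))) { chosen <- a; fwd <- f; break }
  }
  if (is.null(chosen)) {
    stop("no candidate bolus completes the forward (-,+) -> (+,+) -> (+,-) chain",
         call. = FALSE)
  }
  start_b <- stable[stable$quadrant == "+-", , drop = FALSE]
  bwd <- run(start_b[1, ], "X2", chosen)
  list(amount = chosen,
       forward = fwd$trajectory, forward_path = fwd$path,
       backward = bwd$trajectory, backward_path = bwd$path)
}

#' Reporter read-out of a counter trajectory
#'
#' Applies the reporter rate law (activated by `X1`, repressed by `X2`)
#' along a simulated trajectory of the memory circuit, integrating the
#' reporter as a driven linear system.
#'
#' @param trajectory result of [simulate_gma()] with `X1`, `X2` columns.
#' @param pvals reporter parameters (`a4`, `b4`, `rho41`, `rho42`) plus the
#'   circuit's `K1`, `K2`; defaults from the `counter_reporter` fixture.
#' @param x4_0 initial reporter level.
#' @return the trajectory tibble with an `X4` column appended.
#' @export
reporter_readout <- function(trajectory, pvals, x4_0 = NULL) {
  pvals <- unlist(pvals)
  need <- c("a4", "b4", "rho41", "rho42", "K1", "K2")
  miss <- setdiff(need, names(pvals))
  if (length(miss)) stop(sprintf("missing reporter parameter '%s'", miss[1]), call. = FALSE)
  synth <- function(x1, x2) {
    pvals[["a4"]] *
      (pvals[["rho41"]] * x1^2 + pvals[["K1"]]^2) / (x1^2 + pvals[["K1"]]^2) *
      (x2^2 / pvals[["rho42"]] + pvals[["K2"]]^2) / (x2^2 + pvals[["K2"]]^2)
  }
  s <- synth(trajectory$X1, trajectory$X2)
  x4 <- numeric(nrow(trajectory))
  x4[1] <- x4_0 %||% (s[1] / pvals[["b4"]])
  for (i in seq_len(nrow(trajectory) - 1)) {
    dt <- trajectory$time[i + 1] - trajectory$time[i]
    # exact step of dX4/dt = s - b4 X4 with s held at the interval mean
    sm <- (s[i] + s[i + 1]) / 2
    x4[i + 1] <- sm / pvals[["b4"]] + (x4[i] - sm / pvals[["b4"]]) * exp(-pvals[["b4"]] * dt)
  }
  trajectory$X4 <- x4
  trajectory
}
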