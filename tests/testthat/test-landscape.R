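# The slice/basin grids here are deliberately coarse: the properties under
# test (region counts, label consistency, attractor membership) are
# resolution-independent.

bistable_pvals <- function() {
  c(K1 = 1, K3 = 10, X2 = 1, X3 = 1, a1 = 0.32, b1 = 10, rho1 = 100, k = 1)
}

test_that("a slice through the triple-intersection point shows 1- and 3-case regions", {
  sys <- simple_sys()
  sl <- classify_slice(sys, bistable_pvals(), "X2", "b1",
                       c(1e-3, 1e3), c(1e-3, 1e3), resolution = 25)
  expect_true(any(sl$n_cases == 1))
  expect_true(any(sl$n_cases == 3))
  # the filter keeps only requested overlap counts
  fl <- classify_slice(sys, bistable_pvals(), "X2", "b1",
                       c(1e-3, 1e3), c(1e-3, 1e3), resolution = 25,
                       intersections = c(1, 3))
  expect_true(all(is.na(fl$label[!(fl$n_cases %in% c(1, 3))])))
})

test_that("slice labels agree across grid refinement at shared coordinates", {
  sys <- simple_sys()
  a <- classify_slice(sys, bistable_pvals(), "X2", "b1", c(1e-3, 1e3), c(1e-3, 1e3),
                      resolution = 11)
  b <- classify_slice(sys, bistable_pvals(), "X2", "b1", c(1e-3, 1e3), c(1e-3, 1e3),
                      resolution = 21)
  shared <- merge(a, b, by = c("x", "y"))
  expect_gt(nrow(shared), 30)
  expect_identical(shared$label.x, shared$label.y)
})

test_that("slice labels agree with the numeric dominance-ranking oracle", {
  sys <- simple_sys()
  sl <- classify_slice(sys, bistable_pvals(), "X2", "b1",
                       c(1e-2, 1e2), c(1e-2, 1e2), resolution = 7)
  pv <- bistable_pvals()
  for (i in seq_len(nrow(sl))) {
    p <- pv
    p["X2"] <- sl$x[i]; p["b1"] <- sl$y[i]
    labs <- if (sl$label[i] == "") integer(0) else
      as.integer(strsplit(sl$label[i], "+", fixed = TRUE)[[1]])
    # each labeled case's own steady state must rank its dominant terms first
    for (k in labs) {
      cs <- ds_case(sys, k)
      red <- remove_algebraic_constraints(cs$ssystem)
      sol <- solve_steady_state(red)
      y <- as.numeric(sol$gains %*% log10(p[sol$independent])) + sol$intercept
      state <- setNames(10^y, red$dynamic)
      full <- dsdesign:::solve_auxiliaries(sys, c(state, p))
      sig <- integer(0)
      tied <- FALSE
      for (e in sys$equations) {
        for (terms in list(e$pos, e$neg)) {
          v <- vapply(terms, dsdesign:::pl_value, numeric(1), full)
          o <- order(v, decreasing = TRUE)
          # on a region boundary two terms tie and dominance is ambiguous
          if (length(v) > 1 && v[o[2]] > v[o[1]] * (1 - 1e-6)) tied <- TRUE
          sig <- c(sig, o[1])
        }
      }
      if (!tied) expect_equal(case_number(sys, sig), k)
    }
  }
})

test_that("positive-root counts mark bistable overlap regions", {
  sys <- simple_sys()
  # the y-range is offset so that no grid point lands exactly on a
  # dominance boundary (zero-area overlaps are not bistable regions)
  pr <- positive_roots_slice(sys, bistable_pvals(), "X2", "b1",
                             c(1e-3, 1e3), c(1.7e-3, 1.7e3), resolution = 15)
  cl <- classify_slice(sys, bistable_pvals(), "X2", "b1",
                       c(1e-3, 1e3), c(1.7e-3, 1.7e3), resolution = 15)
  expect_setequal(unique(pr$positive_roots), c(0L, 1L))
  # nonzero cells coincide with multi-case overlap cells
  expect_identical(pr$positive_roots > 0, cl$n_cases > 1)
})

test_that("fixed points of the monostable circuit sit at the dominant balance", {
  sys <- simple_sys()
  fp <- find_fixed_points(sys, simple_pvals())
  expect_equal(sum(fp$stable), 1)
  pv <- simple_pvals()
  expect_equal(fp$X1[fp$stable], pv[["a1"]] / pv[["b1"]], tolerance = 0.05)
  expect_true(all(fp$residual < 1e-9))
})

test_that("bistable point yields two stable fixed points separated by a saddle", {
  sys <- simple_sys()
  fp <- find_fixed_points(sys, bistable_pvals())
  expect_equal(sum(fp$stable), 2)
  expect_equal(sum(!fp$stable), 1)
  saddle <- fp$X1[!fp$stable]
  expect_true(min(fp$X1[fp$stable]) < saddle && saddle < max(fp$X1[fp$stable]))
})

test_that("stable fixed points attract a 1 percent perturbation", {
  sys <- simple_sys()
  fp <- find_fixed_points(sys, bistable_pvals())
  for (i in which(fp$stable)) {
    tr <- simulate_gma(sys, bistable_pvals(), c(X1 = fp$X1[i] * 1.01), t_end = 10)
    expect_lt(abs(log10(tr$X1[nrow(tr)]) - log10(fp$X1[i])), 1e-3)
  }
})

test_that("grid ranges must be positive and non-degenerate", {
  sys <- simple_sys()
  expect_error(classify_slice(sys, bistable_pvals(), "X2", "b1", c(1, 1), c(1, 2)),
               "min < max")
})
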