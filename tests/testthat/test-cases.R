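test_that("case number <-> signature bijection matches the printed tables", {
  sys <- simple_sys()
  expect_equal(case_number(sys, "1211"), 4)
  expect_equal(case_number(sys, "3231"), 18)
  expect_equal(case_number(sys, "2131"), 9)
  expect_equal(case_number(sys, "1111"), 1)
  mem <- memory_sys()
  expect_equal(case_number(mem, "32213131"), 297)
  expect_equal(case_number(mem, "11121111"), 10)
  expect_equal(case_number(mem, "32223131"), 306)
  # all-ones signature is case 1 for any system
  expect_equal(case_number(minimal_sys(), c(1, 1)), 1)
  # round trip over every case of both systems
  for (s in list(sys, mem)) {
    for (k in seq_len(prod(system_signature(s)))) {
      expect_equal(case_number(s, case_signature(s, k)), k)
    }
  }
  expect_error(case_number(sys, c(4, 1, 1, 1)), "out of range")
  expect_error(case_signature(sys, 19), "1..18")
})

test_that("dominance conditions have the expected rows", {
  sys <- simple_sys()
  c1 <- ds_case(sys, 1)
  dom <- dominance_conditions(c1)
  # (3-1) + (2-1) + (3-1) + (1-1) = 5 rows
  expect_equal(nrow(dom$A), 5)
  # first row: term1 over term2 of the X1 equation reads
  # -log rho1 - 2 log X1 + 2 log K1 >= 0
  r1 <- setNames(dom$A[1, ], dom$vars)
  expect_equal(unname(r1[c("rho1", "X1", "K1")]), c(-1, -2, 2))
  expect_equal(sum(r1 != 0), 3)
  expect_equal(dom$b[1], 0)
  # an equation with P = Q = 1 contributes no rows
  expect_equal(nrow(dominance_conditions(ds_case(minimal_sys(), 1))$A), 0)
})

test_that("boundary conditions substitute the steady-state solution", {
  sys <- simple_sys()
  c1 <- ds_case(sys, 1)
  bnd <- boundary_conditions(c1)
  expect_identical(bnd$vars, sys$independent)
  # substituting X1 = a1/b1 into the negative-term dominance row gives
  # log b1 - log k - log X2 >= 0
  rows <- apply(bnd$A, 1, function(r) paste(r, collapse = ","))
  neg_row <- setNames(rep(0, length(bnd$vars)), bnd$vars)
  neg_row[c("b1", "k", "X2")] <- c(1, -1, -1)
  expect_true(paste(neg_row[bnd$vars], collapse = ",") %in% rows)
  # and the activation row becomes 2logb1 + 2logK1 - logrho1 - 2loga1 >= 0
  act_row <- setNames(rep(0, length(bnd$vars)), bnd$vars)
  act_row[c("b1", "K1", "rho1", "a1")] <- c(2, 2, -1, -2)
  expect_true(paste(act_row[bnd$vars], collapse = ",") %in% rows)
})

test_that("a dominance row set without dependent variables passes through unchanged", {
  sys <- gma_model(c("X1. = a*s - b*X1 - c*s^2*X1"))
  cs <- ds_case(sys, case_number(sys, c(1, 1)))
  dom <- dominance_conditions(cs)
  bnd <- boundary_conditions(cs)
  dep_free <- which(dom$A[, "X1"] == 0)
  for (i in dep_free) {
    expect_equal(unname(bnd$A[i, ]), unname(dom$A[i, sys$independent]))
  }
})

test_that("contradictory constraint rows make a case invalid", {
  sys <- gma_model("X1. = a - b*X1", constraints = c("a > 10", "a < 0.1"))
  expect_false(case_is_valid(ds_case(sys, 1)))
})

test_that("pointwise partition: numeric term ranking agrees with the dominance polytope", {
  sys <- simple_sys()
  set.seed(77)
  for (i in 1:40) {
    p <- random_point(sys)
    # signature by numeric ranking of term magnitudes
    sig <- integer(0)
    for (e in sys$equations) {
      sig <- c(sig, which.max(vapply(e$pos, dsdesign:::pl_value, numeric(1), p)),
               which.max(vapply(e$neg, dsdesign:::pl_value, numeric(1), p)))
    }
    k <- case_number(sys, sig)
    cs <- ds_case(sys, k)
    y <- log10(p[dominance_conditions(cs)$vars])
    expect_true(dsdesign:::ineq_holds_at(dominance_conditions(cs), y, tol = 1e-9))
  }
})

test_that("validity is invariant to uniform rescaling of an equation's dominant terms", {
  base <- simple_equations()
  sys <- gma_model(base, auxiliaries = "X100", constraints = "rho1 > 1")
  # scale both X1-equation dominant terms of case 8 ([2121]) by 100
  scaled <- c(sub("a1\\*rho1", "100*a1*rho1", sub("b1\\*X1", "100*b1*X1", base[1])),
              base[2])
  sys2 <- gma_model(scaled, auxiliaries = "X100", constraints = "rho1 > 1")
  expect_equal(case_is_valid(ds_case(sys2, 8)), case_is_valid(ds_case(sys, 8)))
})

test_that("monotone infeasibility: adding rows never makes an infeasible system feasible", {
  sys <- simple_sys()
  cases <- lapply(valid_cases(sys), function(k) ds_case(sys, k))
  for (i in seq_along(cases)[-1]) {
    pair <- case_intersection(cases[c(1, i)])
    if (!ensemble_is_valid(pair)) {
      # supersets of the infeasible pair stay infeasible
      for (j in setdiff(seq_along(cases), c(1, i))) {
        expect_false(ensemble_is_valid(case_intersection(cases[c(1, i, j)])))
      }
    }
  }
})
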