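test_that("predicted parameter sets re-validate for their case (closure)", {
  sys <- simple_sys()
  for (k in valid_cases(sys)) {
    cs <- ds_case(sys, k)
    for (pv in list(valid_parameter_set(cs), valid_interior_parameter_set(cs))) {
      expect_true(k %in% valid_cases_at_point(sys, pv), label = paste("case", k))
    }
  }
})

test_that("the printed case-1 witness is valid and its tolerances match the printed table", {
  sys <- simple_sys()
  c1 <- ds_case(sys, 1)
  pv <- simple_pvals()
  expect_true(1 %in% valid_cases_at_point(sys, pv))
  tol <- measure_tolerances(c1, pv)
  get <- function(p, col) tol[[col]][tol$parameter == p]
  expect_equal(get("a1", "fold_increase"), sqrt(10), tolerance = 1e-9)
  expect_equal(get("a1", "fold_decrease"), 1e-20)
  expect_equal(get("b1", "fold_decrease"), 10^-0.5, tolerance = 1e-9)
  expect_equal(get("b1", "fold_increase"), 1e20)
  expect_equal(get("rho1", "fold_decrease"), 0.1, tolerance = 1e-9)
  expect_equal(get("rho1", "fold_increase"), 10, tolerance = 1e-9)
  expect_equal(get("K1", "fold_decrease"), 10^-0.5, tolerance = 1e-9)
  expect_equal(get("K1", "fold_increase"), 1e20)
  expect_equal(get("K3", "fold_decrease"), 0.1, tolerance = 1e-9)
  expect_equal(get("K3", "fold_increase"), 1e20)
  expect_equal(get("k", "fold_increase"), 10, tolerance = 1e-9)
  expect_equal(get("X2", "fold_increase"), 10, tolerance = 1e-9)
  expect_equal(get("X3", "fold_decrease"), 1e-20)
  expect_equal(get("X3", "fold_increase"), 10, tolerance = 1e-9)
})

test_that("tolerance endpoints are tight", {
  sys <- simple_sys()
  c1 <- ds_case(sys, 1)
  pv <- simple_pvals()
  tol <- measure_tolerances(c1, pv)
  for (p in tol$parameter) {
    fi <- tol$fold_increase[tol$parameter == p]
    if (fi < 1e19) {   # away from saturation
      up <- pv; up[p] <- up[p] * fi * 1.0001
      expect_false(1 %in% valid_cases_at_point(sys, up), label = paste(p, "beyond"))
      inb <- pv; inb[p] <- inb[p] * fi * 0.9999
      expect_true(1 %in% valid_cases_at_point(sys, inb), label = paste(p, "within"))
    }
  }
  # a point outside the region is rejected
  bad <- pv; bad["X3"] <- 1e4
  expect_error(measure_tolerances(c1, bad), "outside")
})

test_that("power-law constraints and objectives steer the prediction", {
  sys <- simple_sys()
  c1 <- ds_case(sys, 1)
  pv <- valid_parameter_set(c1, constraints = "X1 > 100")
  # case 1 forces X1 = a1/b1
  expect_gt(pv[["a1"]] / pv[["b1"]], 100)
  pv2 <- valid_parameter_set(c1, bounds = list(X3 = c(1e-3, 1e3)),
                             objective = "X3", maximize = TRUE)
  expect_equal(unname(pv2["X3"]), 1e3, tolerance = 1e-9)
})

test_that("intersections reproduce the printed feasibility pattern", {
  sys <- simple_sys()
  g <- function(k) ds_case(sys, k)
  expect_false(ensemble_is_valid(case_intersection(list(g(1), g(4), g(7)))))
  expect_true(ensemble_is_valid(case_intersection(list(g(1), g(7), g(8)))))
  # singleton intersection equals case validity
  expect_equal(ensemble_is_valid(case_intersection(list(g(1)))), case_is_valid(g(1)))
  # the printed interior witness realizes all three members
  ppt <- c(K1 = 1, K3 = 10, X2 = 1, X3 = 1, a1 = 0.32, b1 = 10, rho1 = 100, k = 1)
  expect_true(all(c(1, 7, 8) %in% valid_cases_at_point(sys, ppt)))
  # and our own prediction re-validates (closure for ensembles)
  pv <- ensemble_parameter_set(case_intersection(list(g(1), g(7), g(8))), interior = TRUE)
  expect_true(all(c(1, 7, 8) %in% valid_cases_at_point(sys, pv)))
  expect_error(case_intersection(list()), "at least one case")
})

test_that("co-localizations over a slice variable reproduce the printed arrangements", {
  sys <- simple_sys()
  cl <- lapply(c(8, 12, 15, 18), function(k) ds_case(sys, k))
  co <- case_colocalization(cl, "X2")
  expect_true(ensemble_is_valid(co))
  asc <- case_colocalization(cl, "X2",
                             constraints = c("$X2_0 < $X2_1", "$X2_1 < $X2_2", "$X2_2 < $X2_3"))
  expect_false(ensemble_is_valid(asc))
  alt <- case_colocalization(cl, "X2",
                             constraints = c("$X2_0 < $X2_1", "$X2_1 > $X2_2",
                                             "$X2_2 < $X2_3", "$X2_1 > $X2_3"))
  expect_true(ensemble_is_valid(alt))
  expect_error(case_colocalization(cl, "Xq"), "not an independent variable")
  expect_error(case_colocalization(cl, "X2", constraints = "$X2_7 > 1"),
               "unknown variable")
})

test_that("the printed co-localization witness satisfies each member's own slice copy", {
  sys <- simple_sys()
  shared <- c(K1 = 1, K3 = 0.1, X3 = 1, a1 = 0.1, b1 = 10, rho1 = 10000, k = 1)
  x2 <- c(`8` = 1, `12` = 100, `15` = 1, `18` = 100)
  for (k in names(x2)) {
    pv <- c(shared, X2 = unname(x2[k]))
    expect_true(as.integer(k) %in% valid_cases_at_point(sys, pv),
                label = paste("case", k, "at its X2 copy"))
  }
  # our own interior prediction re-validates the same way
  co <- case_colocalization(lapply(c(8, 12, 15, 18), function(k) ds_case(sys, k)), "X2")
  ps <- ensemble_parameter_set(co, interior = TRUE)
  repl <- paste0("$X2_", 0:3)
  for (i in seq_along(repl)) {
    pv <- c(ps[sys$independent[sys$independent != "X2"]], X2 = unname(ps[repl[i]]))
    expect_true(c(8, 12, 15, 18)[i] %in% valid_cases_at_point(sys, pv))
  }
})

test_that("pruned intersection search equals exhaustive search on the simple circuit", {
  sys <- simple_sys()
  vc <- valid_cases(sys)
  found <- intersecting_cases(sys, 2:4, vc)
  keys <- sort(vapply(found, function(e) {
    paste(sort(vapply(e$members, function(m) m$number, numeric(1))), collapse = "-")
  }, character(1)))
  # exhaustive oracle
  cases <- lapply(vc, function(k) ds_case(sys, k))
  names(cases) <- vc
  brute <- character(0)
  for (n in 2:4) {
    for (idx in utils::combn(seq_along(vc), n, simplify = FALSE)) {
      if (ensemble_is_valid(case_intersection(cases[idx]))) {
        brute <- c(brute, paste(vc[idx], collapse = "-"))
      }
    }
  }
  expect_identical(keys, sort(brute))
})

test_that("attractor counting distinguishes monostable and multistable points", {
  sys <- simple_sys()
  # negligible activation and repression: the basal phenotype alone
  deep <- c(K1 = 1000, K3 = 1000, X2 = 1, X3 = 1, a1 = 1, b1 = 10, rho1 = 1.5, k = 0.01)
  mono <- count_attractors_at(sys, deep)
  expect_equal(mono$stable, 1)
  expect_equal(mono$unstable, 0)
  tri <- count_attractors_at(sys, c(K1 = 1, K3 = 10, X2 = 1, X3 = 1,
                                    a1 = 0.32, b1 = 10, rho1 = 100, k = 1))
  expect_equal(tri$stable, 2)
  expect_equal(tri$unstable, 1)
})
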