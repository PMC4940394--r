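test_that("case 1 of the autoregulation circuit solves to X1 = a1/b1, X100 = 1", {
  c1 <- ds_case(simple_sys(), 1)
  sol <- solve_steady_state(c1$ssystem)
  expect_true(sol$exists)
  expect_identical(sol$strings, c("X1 = a1*b1^-1", "X100 = 1"))
  expect_equal(unname(sol$gains["X1", c("a1", "b1")]), c(1, -1))
  expect_equal(sum(sol$gains["X100", ] != 0), 0)
})

test_that("removing algebraic constraints yields the reduced dynamic equation", {
  c1 <- ds_case(simple_sys(), 1)
  red <- remove_algebraic_constraints(c1$ssystem)
  expect_identical(deparse_gma(red), "X1. = a1 - b1*X1")
  # a system without auxiliaries is returned unchanged
  tiny <- ds_case(minimal_sys(), 1)
  expect_identical(remove_algebraic_constraints(tiny$ssystem), tiny$ssystem)
})

test_that("constraint elimination preserves right-hand sides numerically", {
  mem <- memory_sys()
  c1 <- ds_case(mem, 1)
  red <- remove_algebraic_constraints(c1$ssystem)
  set.seed(11)
  for (i in 1:20) {
    p <- random_point(mem)
    # solve the S-system's own constraints for the auxiliaries
    for (j in seq_along(mem$auxiliary)) {
      eq <- c1$ssystem$equations[[length(mem$dynamic) + j]]
      p[mem$auxiliary[j]] <- dsdesign:::pl_value(eq$pos[[1]], p) / eq$neg[[1]]$coef
    }
    full <- evaluate_gma(c1$ssystem, p)$net[1:2]
    redv <- evaluate_gma(red, p)$net[1:2]
    expect_lt(max(abs(full - redv) / pmax(abs(full), 1e-300)), 1e-12)
  }
})

test_that("log gains reproduce the printed gain columns", {
  sys <- simple_sys()
  expect_equal(log_gain(ds_case(sys, 1)$ssystem, "X1", "X3"), 0)
  expect_equal(log_gain(ds_case(sys, 4)$ssystem, "X1", "X2"), -1)
  expect_equal(log_gain(ds_case(sys, 9)$ssystem, "X1", "X3"), 1)
  mem <- memory_sys()
  c306 <- ds_case(mem, 306)
  expect_equal(abs(log_gain(c306$ssystem, "X1", "X3")), 0.5)
  expect_equal(log_gain(c306$ssystem, "X2", "X3"), 0.5)
  expect_equal(log_gain(ds_case(mem, 297)$ssystem, "X2", "X3"), 1)
  expect_error(log_gain(c306$ssystem, "Xq", "X3"), "unknown dependent")
})

test_that("gain matrix predicts the first-order response to parameter perturbations", {
  c4 <- ds_case(simple_sys(), 4)
  sol <- solve_steady_state(c4$ssystem)
  pv <- log10(c(a1 = 2, rho1 = 10, K1 = 1, X3 = 1, K3 = 10, b1 = 5, k = 1, X2 = 3))
  eps <- 1e-6
  for (par in c("a1", "k", "X2")) {
    y0 <- as.numeric(sol$gains["X1", names(pv)] %*% pv)
    pv2 <- pv; pv2[par] <- pv2[par] + eps
    y1 <- as.numeric(sol$gains["X1", names(pv)] %*% pv2)
    expect_equal((y1 - y0) / eps, log_gain(c4$ssystem, "X1", par), tolerance = 1e-9)
  }
})

test_that("solution residual vanishes identically", {
  # G y + a = H y + b must hold for the symbolic solution of every
  # solvable case of the simple circuit
  sys <- simple_sys()
  for (k in valid_cases(sys)) {
    cs <- ds_case(sys, k)
    sol <- cs$solution
    m <- dsdesign:::ssys_matrices(cs$ssystem)
    A <- dsdesign:::rat_as_numeric(dsdesign:::rat_sub(m$G, m$H))
    dep <- seq_len(2); ind <- 2 + seq_along(sys$independent)
    # residual of A_dep W + A_ind = 0 and A_dep v = b - a
    res1 <- A[, dep] %*% sol$gains + A[, ind]
    res2 <- A[, dep] %*% sol$intercept - (m$b - m$a)
    expect_lt(max(abs(res1)), 1e-12)
    expect_lt(max(abs(res2)), 1e-12)
  }
})

test_that("a singular dependent block reports no solution", {
  sys <- gma_model(c("X1. = a*X2 - b*X1", "X2. = c - d*X2"))
  expect_true(ds_case(sys, 1)$solution$exists)
  # two equations imposing the same log-linear relation are singular
  sys2 <- gma_model(c("X1. = a*X2 - b*X1", "X2. = c*X1 - d*X2"))
  expect_false(ds_case(sys2, 1)$solution$exists)
})

test_that("eigenvalue analysis matches closed forms and the repertoire stability letters", {
  sys <- simple_sys()
  rep1 <- ssys_eigenvalues(ds_case(sys, 1)$ssystem, simple_pvals())
  expect_equal(rep1$positive_roots, 0)
  expect_equal(Re(rep1$eigenvalues), -10)  # dX1/dt = a1 - b1 X1, b1 = 10
  tiny <- ds_case(minimal_sys(), 1)
  rep2 <- ssys_eigenvalues(tiny$ssystem, c(a = 2, b = 3))
  expect_equal(as.numeric(rep2$eigenvalues), -3)
  tab <- phenotype_table(sys, gain_pairs = list(c("X1", "X2"), c("X1", "X3")))
  expect_identical(tab$stability[match(c(1, 4, 8, 11, 15, 18), tab$case_number)],
                   rep("S", 6))
  expect_identical(tab$stability[match(c(7, 9, 10, 12), tab$case_number)],
                   rep("U", 4))
})

test_that("Routh counts agree with eigenvalue counts on random 2x2 reduced systems", {
  set.seed(99)
  n_checked <- 0
  while (n_checked < 100) {
    g <- sample(c(-2, -1, 0, 1, 2), 8, replace = TRUE)
    eqs <- c(sprintf("X1. = a1*X1^%d*X2^%d - b1*X1^%d*X2^%d", g[1], g[2], g[3], g[4]),
             sprintf("X2. = a2*X1^%d*X2^%d - b2*X1^%d*X2^%d", g[5], g[6], g[7], g[8]))
    sys <- tryCatch(gma_model(eqs), error = function(e) NULL)
    if (is.null(sys)) next
    cs <- ds_case(sys, 1)
    if (!cs$solution$exists) next
    pv <- setNames(10^runif(length(sys$independent), -1, 1), sys$independent)
    er <- tryCatch(ssys_eigenvalues(cs$ssystem, pv), error = function(e) NULL)
    if (is.null(er) || er$borderline) next
    rc <- routh_positive_roots(cs$ssystem, pv)
    if (attr(rc, "method") != "routh") next
    expect_equal(as.integer(rc), er$positive_roots)
    n_checked <- n_checked + 1
  }
})
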