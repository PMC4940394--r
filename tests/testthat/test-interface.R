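test_that("case reports serialize solution, gains and stability to JSON", {
  sys <- simple_sys()
  c1 <- ds_case(sys, 1)
  path <- tempfile(fileext = ".json")
  write_case_report(c1, path, pvals = simple_pvals())
  got <- jsonlite::read_json(path)
  expect_equal(got$case_number, 1)
  expect_equal(got$signature, "1111")
  expect_true("X1 = a1*b1^-1" %in% unlist(got$solution))
  expect_equal(got$positive_roots, 0)
  expect_true(!is.null(got$tolerances))
  unlink(path)
})

test_that("inequality systems export as JSON with rows and relations", {
  c1 <- ds_case(simple_sys(), 1)
  path <- tempfile(fileext = ".json")
  write_ineq_json(boundary_conditions(c1), path)
  got <- jsonlite::read_json(path)
  expect_length(got$coefficients, length(got$constants))
  expect_identical(unlist(got$variables), simple_sys()$independent)
  unlink(path)
})

test_that("tidy and glance methods return well-formed tibbles", {
  c1 <- ds_case(simple_sys(), 1)
  td <- tidy(c1)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("row", "variable", "coefficient") %in% names(td)))
  gl <- glance(c1)
  expect_identical(gl$signature, "1111")
  expect_true(gl$valid)
  sol <- tidy(solve_steady_state(c1$ssystem))
  expect_equal(sol$gain[sol$dependent == "X1" & sol$independent == "a1"], 1)
  st <- ssys_eigenvalues(c1$ssystem, simple_pvals())
  expect_equal(glance(st)$positive_roots, 0)
})

test_that("plot builders return ggplot objects", {
  sys <- simple_sys()
  sl <- classify_slice(sys, c(K1 = 1, K3 = 10, X2 = 1, X3 = 1, a1 = 0.32,
                              b1 = 10, rho1 = 100, k = 1),
                       "X2", "b1", c(1e-2, 1e2), c(1e-2, 1e2), resolution = 8)
  expect_s3_class(plot_slice(sl), "ggplot")
  tr <- simulate_gma(sys, simple_pvals(), c(X1 = 1), t_end = 5, n_out = 20)
  expect_s3_class(plot_trajectory(tr), "ggplot")
})

test_that("the command-line interface enumerates a fixture model", {
  cli <- system.file("cli", "dsdesign.R", package = "dsdesign")
  expect_true(nzchar(cli))
  out <- tempfile()
  res <- system2("Rscript", c(cli, "enumerate", "--model", "simple_circuit",
                              "--out", out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "repertoire.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  rep <- utils::read.csv(file.path(out, "repertoire.csv"))
  expect_equal(sum(rep$valid), 10)
  # model errors exit with status 2
  bad <- suppressWarnings(system2("Rscript", c(cli, "enumerate", "--model",
                                               "no_such_model", "--out", out),
                                  stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 2)
  unlink(out, recursive = TRUE)
})
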