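# The quadrastable memory-circuit instance and the three-state counter.
# Cases {1, 20, 112, 131} form one of the size-4 stable intersections found
# by the ensemble search (re-derived from scratch in the acceptance tests);
# pinning the members here keeps this file focused on the state-space and
# simulation machinery.

quad_instance <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- counter_instance(members = c(1, 20, 112, 131))
    value
  }
})

test_that("the predicted arrangement places one attractor in each quadrant", {
  ci <- quad_instance()
  fp <- ci$fixed_points
  expect_equal(sum(fp$stable), 4)
  expect_setequal(fp$quadrant[fp$stable], c("--", "-+", "+-", "++"))
  expect_true(all(fp$residual < 1e-9))
  # companion unstable fixed points accompany the attractors
  expect_gt(sum(!fp$stable), 0)
  # the same count comes out of the design-space attractor counter
  cnt <- count_attractors_at(ci$system, ci$pvals)
  expect_equal(cnt$stable, 4)
})

test_that("trajectory classes show all four direction classes that meet at attractors", {
  ci <- quad_instance()
  rng <- range(ci$fixed_points$X1) * c(0.1, 10)
  tc <- trajectory_classes(ci$system, ci$pvals, rng, rng, resolution = 25)
  expect_setequal(unique(tc$class), c("NE", "NW", "SE", "SW"))
})

test_that("basins of the quadrastable instance partition the grid into four labels", {
  ci <- quad_instance()
  fp <- ci$fixed_points
  rng <- range(fp$X1[fp$stable]) * c(0.5, 2)
  bs <- basins(ci$system, ci$pvals, rng, rng, resolution = 9,
               fixed_points = fp, t_cap = 2000)
  expect_setequal(unique(stats::na.omit(bs$attractor)), seq_len(4))
  # grid points placed at the attractors label themselves
  st <- fp[fp$stable, ]
  for (i in seq_len(nrow(st))) {
    b1 <- basins(ci$system, ci$pvals, c(st$X1[i], st$X1[i] * 1.0001),
                 c(st$X2[i], st$X2[i] * 1.0001), resolution = 2,
                 fixed_points = fp, t_cap = 10)
    expect_true(all(b1$attractor == i))
  }
})

test_that("the counter steps forward with X1 boluses and back with X2 boluses", {
  ci <- quad_instance()
  demo <- counter_demo(ci)
  expect_identical(demo$forward_path, c("-+", "++", "+-"))
  expect_identical(demo$backward_path, c("+-", "++", "-+"))
  # states stay strictly positive throughout
  expect_true(all(as.matrix(demo$forward[, c("X1", "X2")]) > 0))
})

test_that("the reporter visits three strictly ordered levels along the count", {
  ci <- quad_instance()
  demo <- counter_demo(ci)
  rp <- c(dsd_fixture("counter_reporter")$pvals, ci$pvals[c("K1", "K2")])
  tr <- reporter_readout(demo$forward, rp)
  levels <- vapply(c(19.9, 39.9, 59.9), function(t) tr$X4[which.min(abs(tr$time - t))],
                   numeric(1))
  expect_true(all(diff(levels) > 0))
  expect_gt(levels[3] / levels[1], 5)
})
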