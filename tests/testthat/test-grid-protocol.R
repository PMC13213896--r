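test_that("conservative bounds take the extreme endpoints across sites", {
  b <- conservative_bounds(c(0.25, 0.31, 0.21, 0.09, 0.21),
                           c(0.90, 0.63, 0.53, 0.24, 0.73))
  expect_equal(unname(b), c(0.09, 0.90))
  expect_equal(unname(conservative_bounds(-1, 2)), c(-1, 2))
  expect_equal(unname(conservative_bounds(rep(0.1, 5), rep(0.4, 5))),
               c(0.1, 0.4))
  expect_error(conservative_bounds(numeric(0), numeric(0)), "at least one")
  expect_error(conservative_bounds(c(0, 1), c(2, 0.5)), "lower < upper")
})

test_that("axes are built by integer indexing from the exact lower anchor", {
  a <- build_axis("b", 0.00, 0.03, 0.01)
  expect_equal(a$values, c(0.00, 0.01, 0.02, 0.03))

  a2 <- build_axis("hypertension", 0.09, 0.90, 0.01)
  expect_length(a2$values, 82)
  expect_equal(a2$values[82], 0.90, tolerance = 1e-12)

  # unrounded anchor, endpoint short of the bound when not a multiple
  a3 <- build_axis("hypertension", 0.0876, 0.2392, 0.005)
  expect_identical(a3$values[1], 0.0876)
  expect_length(a3$values, 31)
  expect_equal(a3$values[31], 0.2376, tolerance = 1e-12)

  # bit-reproducible: identical construction gives identical doubles
  expect_identical(a3$values,
                   build_axis("hypertension", 0.0876, 0.2392, 0.005)$values)

  expect_error(build_axis("b", 0, 1, 0), "increment")
  expect_error(build_axis("b", 1, 1, 0.1), "lower < upper")
})

test_that("axis construction properties hold over random bounds", {
  set.seed(303)
  for (i in 1:50) {
    lo <- runif(1, -5, 5)
    width <- runif(1, 0.001, 3)
    inc <- sample(c(0.01, 0.005, 0.02, 0.037), 1)
    a <- build_axis("p", lo, lo + width, inc)
    expect_identical(a$values[1], lo)
    if (length(a$values) > 1) {
      expect_equal(max(abs(diff(a$values) - inc)), 0, tolerance = 1e-12)
    }
    last <- a$values[length(a$values)]
    expect_lte(last, lo + width + 1e-9)
    expect_gt(last, lo + width - inc)

    # halving the increment at least doubles the number of steps
    a_half <- build_axis("p", lo, lo + width, inc / 2)
    expect_gte(length(a_half$values) - 1, 2 * (length(a$values) - 1))
  }
})

test_that("grid specs union the site intervals and anchor unrounded bounds", {
  f1 <- fake_fit(c(b = 0.05), c(b = 0.1 / (2 * qnorm(0.975))))
  f2 <- fake_fit(c(b = 0.125), c(b = 0.15 / (2 * qnorm(0.975))), "s2")
  g <- build_grid_spec(list(f1, f2), 0.05)
  expect_equal(g$axes[[1]]$values, c(0, 0.05, 0.10, 0.15, 0.20),
               tolerance = 1e-9)

  sets <- lapply(1:5, function(i) {
    fit_local(random_dataset(400, c(-0.2, 0.5, -0.8), seed = 100 + i,
                             site_id = paste0("s", i)), toy_spec2)
  })
  g2 <- build_grid_spec(sets, 0.01)
  lowers <- sapply(sets, function(f) f$ci_lower)
  uppers <- sapply(sets, function(f) f$ci_upper)
  for (j in 1:3) {
    ax <- g2$axes[[j]]
    expect_identical(ax$lower, min(lowers[j, ]))   # exact, unrounded anchor
    expect_true(all(lowers[j, ] >= ax$lower & uppers[j, ] <= ax$upper))
  }

  # refinement nesting: 0.005 axes contain every 0.01 value
  g3 <- build_grid_spec(sets, 0.005)
  for (j in 1:3) {
    coarse <- g2$axes[[j]]$values
    fine <- g3$axes[[j]]$values
    expect_true(all(vapply(coarse,
                           function(v) min(abs(fine - v)) < 1e-12, TRUE)))
  }
})

test_that("grid specs refuse inconsistent model structures", {
  f1 <- fake_fit(c(a = 0, b = 1), c(a = 0.1, b = 0.1), "s1")
  f2 <- fake_fit(c(a = 0, c = 1), c(a = 0.1, c = 0.1), "s2")
  expect_error(build_grid_spec(list(f1, f2), 0.01), "identical model")
  f3 <- fake_fit(c(a = 0, b = 1), c(a = 0.1, b = 0.1), "s3")
  f3$converged <- FALSE
  expect_error(build_grid_spec(list(f1, f3), 0.01), "converge")
})

test_that("grid size is the product of axis lengths, overflow-safe", {
  g <- grid_spec(list(build_axis("a", 0, 0.01, 0.01),
                      build_axis("b", 0, 0.02, 0.01)), 0.01)
  expect_equal(grid_size(g), 6)

  # the axis lengths implied by the case study's rounded intervals
  g2 <- grid_spec(list(
    build_axis("i", 0, 1.99, 0.01),      # 200 values
    build_axis("h", 0, 0.81, 0.01),      # 82
    build_axis("s", 0, 0.68, 0.01),      # 69
    build_axis("a", 0, 0.03, 0.01)       # 4
  ), 0.01)
  expect_identical(vapply(g2$axes, function(a) length(a$values), 0L),
                   c(200L, 82L, 69L, 4L))
  expect_equal(grid_size(g2), 4526400)

  g3 <- grid_spec(list(build_axis("x", 0, 0.004, 0.01)), 0.01)
  expect_equal(grid_size(g3), 1)   # degenerate single-value axis

  big <- grid_spec(lapply(1:4, function(j) {
    build_axis(paste0("p", j), 0, 3, 0.01 / j)
  }), 0.01)
  expect_gt(grid_size(big), 1e9)   # no integer overflow
})

test_that("fingerprints change iff names, bounds or increment change", {
  axes <- list(build_axis("a", -1, 1, 0.01), build_axis("b", 0, 2, 0.01))
  g <- grid_spec(axes, 0.01)
  expect_identical(g$fingerprint, grid_spec(axes, 0.01)$fingerprint)

  shifted <- grid_spec(list(build_axis("a", -1 + 1e-12, 1, 0.01),
                            axes[[2]]), 0.01)
  expect_false(identical(g$fingerprint, shifted$fingerprint))
  renamed <- grid_spec(list(build_axis("z", -1, 1, 0.01), axes[[2]]), 0.01)
  expect_false(identical(g$fingerprint, renamed$fingerprint))
  finer <- grid_spec(lapply(axes, function(a) {
    build_axis(a$name, a$lower, a$upper, 0.005)
  }), 0.005)
  expect_false(identical(g$fingerprint, finer$fingerprint))
})

test_that("grid specs round-trip through the JSON artifact", {
  g <- grid_spec(list(build_axis("a", -0.123456789, 1.1, 0.01),
                      build_axis("b", 0, 2, 0.01)), 0.01)
  path <- withr::local_tempfile(fileext = ".json")
  write_grid_spec(g, path)
  back <- read_grid_spec(path)
  expect_identical(back$fingerprint, g$fingerprint)
  expect_identical(back$axes[[1]]$values, g$axes[[1]]$values)
})
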