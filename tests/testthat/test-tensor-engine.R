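test_that("tensor evaluation equals the cellwise oracle", {
  d <- random_dataset(20, c(-0.4, 0.9), seed = 21)
  spec <- spec_for(d)
  g <- grid_spec(list(build_axis("(Intercept)", -1, -0.6, 0.1),
                      build_axis("x1", 0.5, 1.1, 0.2)), 0.1)
  tens <- evaluate_tensor(d, spec, g)
  expect_equal(tens$values, oracle_tensor_values(d, spec, g),
               tolerance = 1e-12)
  expect_true(all(tens$values <= 0))
  expect_equal(tens$max_value, max(tens$values))
})

test_that("a single-cell grid holds exactly one log-likelihood value", {
  d <- random_dataset(15, c(0.2, -0.5), seed = 3)
  spec <- spec_for(d)
  g <- grid_spec(list(build_axis("(Intercept)", 0.2, 0.2005, 0.01),
                      build_axis("x1", -0.5, -0.4995, 0.01)), 0.01)
  tens <- evaluate_tensor(d, spec, g)
  expect_length(tens$values, 1)
  expect_equal(tens$values, log_likelihood(d, spec, c(0.2, -0.5)))
})

test_that("chunking partitions cells without changing a single bit", {
  d <- random_dataset(50, c(0.1, 0.7), seed = 8)
  spec <- spec_for(d)
  g <- grid_spec(list(build_axis("(Intercept)", -1, 1, 0.25),
                      build_axis("x1", -1, 1, 0.25)), 0.25)
  t_one <- evaluate_tensor(d, spec, g, chunk_cells = 1)
  t_mid <- evaluate_tensor(d, spec, g, chunk_cells = 7)
  t_all <- evaluate_tensor(d, spec, g, chunk_cells = 1000)
  expect_identical(t_one$values, t_all$values)
  expect_identical(t_mid$values, t_all$values)
})

test_that("evaluation refuses misaligned grids and oversized lattices", {
  d <- random_dataset(10, c(0, 1), seed = 4)
  spec <- spec_for(d)
  wrong <- grid_spec(list(build_axis("x1", -1, 1, 0.5),
                          build_axis("(Intercept)", -1, 1, 0.5)), 0.5)
  expect_error(evaluate_tensor(d, spec, wrong), "do not match")

  g <- grid_spec(list(build_axis("(Intercept)", -1, 1, 0.01),
                      build_axis("x1", -1, 1, 0.01)), 0.01)
  expect_error(evaluate_tensor(d, spec, g, memory_limit = 1000), "ceiling")
})

test_that("argmax returns the maximising cell with a deterministic tie rule", {
  g <- grid_spec(list(build_axis("a", 0, 0.2, 0.1),
                      build_axis("b", 0, 0.3, 0.1)), 0.1)
  vals <- rep(-5, 12)
  vals[7] <- -1                       # cell (2, 3) in row-major order
  tens <- tensor_from_values(vals, g)
  am <- argmax_cell(tens)
  expect_equal(am$indices, c(2, 3))
  expect_equal(unname(am$beta), c(0.1, 0.2))
  expect_equal(am$max_loglik, -1)

  flat <- tensor_from_values(rep(-2, 12), g)
  expect_equal(argmax_cell(flat)$indices, c(1, 1))   # lowest row-major index
})

test_that("the relative-likelihood region matches its definition", {
  g <- grid_spec(list(build_axis("a", 0, 0.4, 0.1)), 0.1)
  tens <- tensor_from_values(c(-3, -1.5, -1, -1.9, -4), g)
  mask <- relative_likelihood_region(tens, 0.147)
  expect_identical(mask, c(-3, -1.5, -1, -1.9, -4) >= -1 + log(0.147))
  expect_true(mask[argmax_cell(tens)$indices[1]])

  exact <- relative_likelihood_region(tens, 1)
  expect_identical(which(exact), 3L)
  expect_error(relative_likelihood_region(tens, 0), "threshold")
})

test_that("regions of quadratic surfaces match the analytic ellipsoid", {
  # exact Gaussian log-likelihood surface: ll = -0.5 (b - m)' I (b - m)
  ax <- list(build_axis("a", -1, 1, 0.05), build_axis("b", -1, 1, 0.05))
  g <- grid_spec(ax, 0.05)
  m <- c(0.1, -0.2)
  I <- matrix(c(40, 12, 12, 25), 2)
  cells <- as.matrix(expand.grid(b = ax[[2]]$values, a = ax[[1]]$values))
  # expand.grid varies the first factor fastest; row-major order needs the
  # LAST axis fastest, so build columns in reverse and swap back
  B <- cbind(cells[, "a"], cells[, "b"])
  qf <- rowSums((B - rep(m, each = nrow(B))) %*% I *
                  (B - rep(m, each = nrow(B))))
  tens <- tensor_from_values(-0.5 * qf, g)

  # the mode lies on the lattice, so the grid maximum is exactly m and
  # the region must equal the analytic ellipsoid
  # {b : (b - m)' I (b - m) <= -2 log(threshold)} cell for cell
  expect_true(all(abs(B[which.max(-0.5 * qf), ] - m) < 1e-12))
  for (thr in c(0.147, 0.5, 0.9)) {
    mask <- relative_likelihood_region(tens, thr)
    expect_identical(mask, qf <= -2 * log(thr))
  }
})

test_that("likelihood intervals project the region onto each axis", {
  # symmetric 1-axis quadratic surface: ll = -(b - 0.3)^2 / (2 sigma^2)
  sigma <- 0.07
  ax <- build_axis("a", 0, 0.6, 0.005)
  g <- grid_spec(list(ax), 0.005)
  tens <- tensor_from_values(-(ax$values - 0.3)^2 / (2 * sigma^2), g)
  thr <- 0.147
  li <- likelihood_interval(tens, 1, thr)
  half <- sigma * sqrt(-2 * log(thr))
  expect_lt(abs(li[["upper"]] - li[["lower"]] - 2 * half), 2 * 0.005)
  mid <- (li[["upper"]] + li[["lower"]]) / 2
  expect_lt(abs(mid - 0.3), 1e-9)     # symmetric about the argmax

  # 0.147 vs the chi-square calibrated cutoff: at most one grid step apart
  li_cal <- likelihood_interval(tens, 1, exp(-qchisq(0.95, 1) / 2))
  expect_lte(abs(li_cal[["lower"]] - li[["lower"]]), 0.005 + 1e-12)
  expect_lte(abs(li_cal[["upper"]] - li[["upper"]]), 0.005 + 1e-12)

  # single-cell region projects to a degenerate interval on every axis
  g2 <- grid_spec(list(build_axis("a", 0, 0.2, 0.1),
                       build_axis("b", 0, 0.2, 0.1)), 0.1)
  vals <- rep(-50, 9); vals[5] <- 0
  tens2 <- tensor_from_values(vals, g2)
  expect_equal(unname(likelihood_interval(tens2, 1)), c(0.1, 0.1))
  expect_equal(unname(likelihood_interval(tens2, "b")), c(0.1, 0.1))
})

test_that("the grid maximum never beats the continuous optimiser", {
  d <- random_dataset(500, c(-0.3, 0.6, -0.2), seed = 33)
  spec <- spec_for(d)
  fit <- fit_local(d, spec)
  g_coarse <- grid_spec(lapply(seq_along(fit$parameters), function(j) {
    build_axis(fit$parameters[j], fit$estimates[j] - 0.3,
               fit$estimates[j] + 0.3, 0.04)
  }), 0.04)
  t_coarse <- evaluate_tensor(d, spec, g_coarse)
  expect_lte(t_coarse$max_value, fit$max_loglik)

  # refining on the same bounds keeps the coarse lattice as a sublattice,
  # so the maximum can only improve
  g_fine <- grid_spec(lapply(g_coarse$axes, function(a) {
    build_axis(a$name, a$lower, a$upper, 0.02)
  }), 0.02)
  t_fine <- evaluate_tensor(d, spec, g_fine)
  expect_gte(t_fine$max_value, t_coarse$max_value)
  expect_lte(t_fine$max_value, fit$max_loglik)
})

test_that("tensors round-trip through the header + payload artifact", {
  d <- random_dataset(30, c(0.2, -0.7), seed = 12)
  spec <- spec_for(d)
  g <- grid_spec(list(build_axis("(Intercept)", -0.5, 0.5, 0.1),
                      build_axis("x1", -1.2, 0, 0.1)), 0.1)
  tens <- evaluate_tensor(d, spec, g)
  stem <- file.path(withr::local_tempdir(), "site_a")
  write_tensor(tens, stem)
  back <- read_tensor(stem)
  expect_identical(back$values, tens$values)
  expect_identical(back$grid_fingerprint, tens$grid_fingerprint)
  expect_identical(back$axis_values, tens$axis_values)
  expect_equal(back$n_observations, tens$n_observations)
})
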