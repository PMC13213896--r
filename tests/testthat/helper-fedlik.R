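# Shared fixtures and independent oracles, all built in code.

toy_spec <- model_spec("y", "x")
toy_spec2 <- model_spec("y", c("x1", "x2"))

# Bernoulli draws with a logistic outcome model; plain base-R generation,
# independent of the package's synthetic-data module.
random_dataset <- function(n, beta, seed, site_id = "toy") {
  set.seed(seed)
  p <- length(beta) - 1L
  X <- matrix(rnorm(n * p), n, p)
  eta <- beta[1] + X %*% beta[-1]
  df <- data.frame(y = rbinom(n, 1, plogis(eta)))
  for (j in seq_len(p)) df[[paste0("x", j)]] <- X[, j]
  site_dataset(df, site_id)
}

spec_for <- function(dataset) {
  covs <- setdiff(names(dataset$data), "y")
  model_spec("y", covs)
}

# Independent per-record log-likelihood oracle: explicit loop through
# dbinom, no shared code with log_likelihood().
oracle_loglik <- function(dataset, spec, beta) {
  total <- 0
  for (i in seq_len(dataset$n)) {
    row <- dataset$data[i, ]
    eta <- beta[1] + sum(beta[-1] * as.numeric(row[spec$covariates]))
    total <- total + dbinom(row[[spec$outcome]], 1, plogis(eta), log = TRUE)
  }
  total
}

# Brute-force tensor oracle: nested iteration over every cell, calling
# log_likelihood() once per cell (row-major, last axis fastest).
oracle_tensor_values <- function(dataset, spec, grid) {
  lengths <- vapply(grid$axes, function(a) length(a$values), 0L)
  cells <- prod(lengths)
  out <- numeric(cells)
  for (i in seq_len(cells)) {
    rem <- i - 1
    k <- integer(length(lengths))
    for (j in length(lengths):1) {
      k[j] <- rem %% lengths[j] + 1
      rem <- rem %/% lengths[j]
    }
    beta <- vapply(seq_along(k), function(j) grid$axes[[j]]$values[k[j]], 0)
    out[i] <- log_likelihood(dataset, spec, beta)
  }
  out
}

# Synthetic local fit with prescribed estimates/SEs (for grid tests that
# need exact confidence intervals).
fake_fit <- function(estimates, se, site_id = "fake",
                     parameters = names(estimates)) {
  stopifnot(!is.null(parameters))
  z <- qnorm(0.975)
  structure(
    list(site_id = site_id, parameters = parameters,
         estimates = setNames(estimates, parameters),
         se = setNames(se, parameters),
         ci_lower = setNames(estimates - z * se, parameters),
         ci_upper = setNames(estimates + z * se, parameters),
         vcov = NULL, max_loglik = -1, converged = TRUE,
         n_iter = 1L, n = 100L),
    class = "fl_local_fit"
  )
}

# Tensor with prescribed cell values (e.g. exact quadratic surfaces).
tensor_from_values <- function(values, grid, site_id = "synthetic", n = 1L) {
  fedlik:::new_loglik_tensor(values, grid, site_id, n)
}
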