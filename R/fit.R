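#' Fit the site-local logistic regression by IRLS
#'
#' Round 1 of the protocol, run inside each jurisdiction: maximum
#' likelihood via iteratively reweighted least squares (Fisher scoring,
#' which equals Newton for the logit link), with standard errors from the
#' inverse observed information at the optimum and 95% Wald confidence
#' intervals. Only the resulting aggregate summary -- not the records --
#' is shared with the coordinator.
#'
#' Degenerate configurations are refused loudly rather than returning
#' unusable numbers: a single-class outcome (a site with no events cannot
#' contribute a regression, and must be excluded from the network) and
#' complete or quasi-complete separation (non-finite maximiser, detected
#' through divergent coefficients, a singular information matrix, or IRLS
#' non-convergence).
#'
#' @param dataset An [site_dataset()].
#' @param spec An [model_spec()].
#' @param tol Convergence tolerance on the relative deviance change
#'   between IRLS iterations.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `fl_local_fit`: `site_id`, `parameters`,
#'   `estimates`, `se`, `ci_lower`/`ci_upper` (95% Wald), `vcov`,
#'   `max_loglik`, `converged`, `n_iter`, `n`.
#' @export
fit_local <- function(dataset, spec, tol = 1e-8, max_iter = 50L) {
  dm <- design_matrix(dataset, spec)
  X <- dm$X
  y <- dm$y
  p <- ncol(X)
  if (length(unique(y)) < 2L) {
    stop("site '", dataset$site_id, "': outcome '", spec$outcome,
         "' has a single class (no recorded patients with",
         if (all(y == 1)) "out" else "", " the outcome); ",
         "the site cannot be fit and must be excluded", call. = FALSE)
  }
  if (dataset$n <= p) {
    stop("site '", dataset$site_id, "': n (", dataset$n,
         ") must exceed the parameter count (", p, ")", call. = FALSE)
  }

  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  ))
  beta <- fit$coefficients

  # Observed information I(beta) = X' W X, W = mu (1 - mu); for the logit
  # link this equals the expected information.
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))

  separated <- !fit$converged ||
    anyNA(beta) ||
    any(abs(beta) > 15) ||
    !is.finite(rcond(info)) || rcond(info) < 1e-12
  if (separated) {
    stop("site '", dataset$site_id, "': logistic fit did not converge to a ",
         "finite maximum (complete or quasi-complete separation, or ",
         "singular information); estimates are unusable", call. = FALSE)
  }

  vcov <- chol2inv(chol(info))
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- spec$parameters
  dimnames(vcov) <- list(spec$parameters, spec$parameters)

  out <- structure(
    list(
      site_id = dataset$site_id,
      parameters = spec$parameters,
      estimates = beta,
      se = se,
      ci_lower = NULL, ci_upper = NULL,
      vcov = vcov,
      max_loglik = log_likelihood(dataset, spec, beta),
      converged = TRUE,
      n_iter = fit$iter,
      n = dataset$n
    ),
    class = "fl_local_fit"
  )
  ci <- wald_ci(out, 0.95)
  out$ci_lower <- ci[, "lower"]
  out$ci_upper <- ci[, "upper"]
  out
}

#' Wald confidence intervals for a local fit
#'
#' `estimate +- z * SE` per parameter, using the exact standard-normal
#' quantile (1.959964... at `level = 0.95`, not the rounded 1.96).
#'
#' @param fit An `fl_local_fit`.
#' @param level Confidence level in (0, 1).
#' @return Matrix with columns `lower`, `upper`, one row per parameter.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fl_local_fit"))
  if (!isTRUE(fit$converged)) {
    stop("confidence intervals are undefined for a non-converged fit", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single value in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = fit$estimates - z * fit$se,
        upper = fit$estimates + z * fit$se)
}

#' @export
print.fl_local_fit <- function(x, digits = 4, ...) {
  cat("Local logistic fit -- site '", x$site_id, "' (n = ", x$n, ")\n", sep = "")
  tab <- cbind(estimate = x$estimates, se = x$se,
               ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  print(round(tab, digits))
  cat("max log-likelihood:", format(x$max_loglik, digits = digits + 3),
      " (", x$n_iter, "IRLS iterations )\n")
  invisible(x)
}

#' Serialise a local fit to JSON (the round-1 site message)
#'
#' The JSON summary (estimates, SEs, CIs, maximum log-likelihood, n) is
#' the only artifact a site shares in round 1; the coordinator uses the
#' confidence intervals to construct the shared parameter lattice.
#'
#' @param fit An `fl_local_fit`.
#' @param path Output path.
#' @return `path`, invisibly; `read_local_fit()` returns the fit.
#' @export
write_local_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fl_local_fit"))
  obj <- list(
    schema = "fedlik/local_fit/1",
    site_id = fit$site_id,
    parameters = fit$parameters,
    estimates = unname(fit$estimates),
    se = unname(fit$se),
    ci_lower = unname(fit$ci_lower),
    ci_upper = unname(fit$ci_upper),
    max_loglik = fit$max_loglik,
    converged = fit$converged,
    n_iter = fit$n_iter,
    n = fit$n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_local_fit
#' @export
read_local_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "fedlik/local_fit/1")) {
    stop("not a fedlik local-fit artifact: ", path, call. = FALSE)
  }
  est <- stats::setNames(obj$estimates, obj$parameters)
  structure(
    list(
      site_id = obj$site_id,
      parameters = obj$parameters,
      estimates = est,
      se = stats::setNames(obj$se, obj$parameters),
      ci_lower = stats::setNames(obj$ci_lower, obj$parameters),
      ci_upper = stats::setNames(obj$ci_upper, obj$parameters),
      vcov = NULL,
      max_loglik = obj$max_loglik,
      converged = obj$converged,
      n_iter = obj$n_iter,
      n = obj$n
    ),
    class = "fl_local_fit"
  )
}
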