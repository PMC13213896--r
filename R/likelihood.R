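# Numerically stable softplus: log(1 + exp(x)) without overflow for
# |x| up to well beyond +-700. pmax/abs keep it elementwise-deterministic,
# so results are bitwise identical however the input is chunked.
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Bernoulli log-likelihood of a logistic model at a parameter vector
#'
#' Computes \eqn{\ell(\beta) = \sum_i [y_i \eta_i - \log(1 + e^{\eta_i})]}
#' with \eqn{\eta_i = x_i^T \beta}, summing records in dataset order. The
#' softplus term is evaluated piecewise so the result stays finite for
#' linear predictors up to around +-700.
#'
#' This evaluator is the primitive every protocol stage shares: local
#' model fits report their maximum through it, and the lattice tensors
#' are built by calling it (vectorised) at every grid cell.
#'
#' @param dataset An [site_dataset()] object.
#' @param spec An [model_spec()] object.
#' @param beta Numeric parameter vector, intercept first; length must
#'   equal `1 + length(spec$covariates)`.
#' @return A finite scalar, always `<= 0`.
#' @examples
#' d <- site_dataset(data.frame(y = c(0, 1), x = c(0, 1)), "toy")
#' log_likelihood(d, model_spec("y", "x"), c(0, 0))  # 2 * log(0.5)
#' @export
log_likelihood <- function(dataset, spec, beta) {
  dm <- design_matrix(dataset, spec)
  p <- ncol(dm$X)
  if (length(beta) != p) {
    stop("parameter vector has length ", length(beta),
         " but the model has ", p, " parameters", call. = FALSE)
  }
  eta <- drop(dm$X %*% as.double(beta))
  sum(dm$y * eta - softplus(eta))
}
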