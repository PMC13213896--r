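#' Common-effect inverse-variance meta-analysis of site estimates
#'
#' The comparator method: pools per-site coefficient estimates under the
#' assumption of one shared true effect, weighting each site by the
#' inverse of its squared standard error. Each model parameter is pooled
#' in its own meta-analysis. Heterogeneity is summarised by Cochran's Q,
#' its chi-square p-value, and I-squared.
#'
#' @param estimate Numeric vector of per-site estimates (log-odds
#'   scale).
#' @param se Per-site standard errors, all `> 0`.
#' @param labels Optional site labels.
#' @param level Confidence level for the pooled Wald interval.
#' @return An object of class `fl_meta_result`: `pooled`, `pooled_se`,
#'   `ci`, `weights` (normalised to sum 1), `Q`, `df`,
#'   `p_heterogeneity`, `i_squared`, `k`, plus the inputs.
#' @examples
#' pool_inverse_variance(
#'   c(0.5660, 0.4661, 0.3651, 0.1634, 0.4664),
#'   c(0.1661, 0.0823, 0.0820, 0.0387, 0.1302)
#' )
#' @export
pool_inverse_variance <- function(estimate, se, labels = NULL, level = 0.95) {
  stopifnot(is.numeric(estimate), is.numeric(se),
            length(estimate) == length(se), length(estimate) >= 1L)
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("all standard errors must be finite and > 0", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("site_", seq_along(estimate))
  k <- length(estimate)
  w <- 1 / se^2
  pooled <- sum(w * estimate) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (k >= 2L) {
    Q <- cochran_q(estimate, se, pooled)
    df <- k - 1L
    p_het <- heterogeneity_p(Q, df)
    i2 <- i_squared(Q, k)
  } else {
    Q <- NA_real_; df <- 0L; p_het <- NA_real_; i2 <- NA_real_
  }
  structure(
    list(
      pooled = pooled, pooled_se = pooled_se,
      ci = c(lower = pooled - z * pooled_se, upper = pooled + z * pooled_se),
      level = level,
      weights = stats::setNames(w / sum(w), labels),
      Q = Q, df = df, p_heterogeneity = p_het, i_squared = i2,
      k = k,
      estimate = stats::setNames(estimate, labels),
      se = stats::setNames(se, labels)
    ),
    class = "fl_meta_result"
  )
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the site estimates from the
#' pooled estimate, \eqn{Q = \sum_i w_i (\theta_i - \bar\theta)^2} with
#' \eqn{w_i = 1/SE_i^2}; chi-square with `k - 1` degrees of freedom
#' under homogeneity.
#'
#' @inheritParams pool_inverse_variance
#' @param pooled The pooled estimate the deviations are taken from.
#' @return Scalar `Q >= 0`.
#' @export
cochran_q <- function(estimate, se, pooled) {
  stopifnot(length(estimate) == length(se))
  if (length(estimate) < 2L) {
    stop("Cochran's Q requires at least two sites", call. = FALSE)
  }
  if (any(se <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  sum((estimate - pooled)^2 / se^2)
}

#' I-squared heterogeneity proportion
#'
#' The proportion of total variation in the site effects attributable to
#' true heterogeneity rather than chance: `(Q - (k - 1)) / Q`, clamped
#' at zero whenever `Q` falls below its homogeneity expectation.
#'
#' @param Q Cochran's Q.
#' @param k Number of sites, `>= 2`.
#' @return Proportion in `[0, 1)`.
#' @export
i_squared <- function(Q, k) {
  stopifnot(Q >= 0, k >= 2)
  if (Q == 0) return(0)
  max(0, (Q - (k - 1)) / Q)
}

#' Chi-square p-value for heterogeneity
#'
#' Upper tail of the chi-square distribution with `df = k - 1` degrees
#' of freedom evaluated at Q.
#'
#' @param Q Cochran's Q.
#' @param df Degrees of freedom, `>= 1`.
#' @return p-value in `(0, 1]`.
#' @export
heterogeneity_p <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  stats::pchisq(Q, df, lower.tail = FALSE)
}

#' Forest-plot rows for one parameter's meta-analysis
#'
#' One row per site (estimate, Wald CI, percent weight) followed by the
#' pooled row; weights sum to 100%.
#'
#' @param meta An `fl_meta_result`.
#' @return A `data.frame` with columns `label`, `estimate`, `ci_lower`,
#'   `ci_upper`, `weight_pct`, `pooled` (flag).
#' @export
forest_data <- function(meta) {
  stopifnot(inherits(meta, "fl_meta_result"))
  z <- stats::qnorm(1 - (1 - meta$level) / 2)
  rbind(
    data.frame(
      label = names(meta$estimate),
      estimate = unname(meta$estimate),
      ci_lower = unname(meta$estimate - z * meta$se),
      ci_upper = unname(meta$estimate + z * meta$se),
      weight_pct = unname(100 * meta$weights),
      pooled = FALSE
    ),
    data.frame(
      label = "pooled (common effect)",
      estimate = meta$pooled,
      ci_lower = meta$ci[["lower"]],
      ci_upper = meta$ci[["upper"]],
      weight_pct = 100,
      pooled = TRUE
    )
  )
}

#' @export
print.fl_meta_result <- function(x, digits = 4, ...) {
  cat("Common-effect meta-analysis (", x$k, " sites)\n", sep = "")
  cat("  pooled ", round(x$pooled, digits), " (SE ", round(x$pooled_se, digits),
      "), ", 100 * x$level, "% CI (", round(x$ci[["lower"]], digits), ", ",
      round(x$ci[["upper"]], digits), ")\n", sep = "")
  if (x$k >= 2L) {
    cat("  Q = ", round(x$Q, 2), " (df ", x$df, ", p = ",
        format.pval(x$p_heterogeneity, digits = 2), "), I2 = ",
        round(100 * x$i_squared), "%\n", sep = "")
  }
  invisible(x)
}

#' Serialise a meta-analysis result to JSON
#'
#' @param meta An `fl_meta_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_result <- function(meta, path) {
  stopifnot(inherits(meta, "fl_meta_result"))
  obj <- list(
    schema = "fedlik/meta_result/1",
    pooled = meta$pooled, pooled_se = meta$pooled_se,
    ci_lower = meta$ci[["lower"]], ci_upper = meta$ci[["upper"]],
    level = meta$level,
    Q = meta$Q, df = meta$df,
    p_heterogeneity = meta$p_heterogeneity, i_squared = meta$i_squared,
    k = meta$k,
    sites = names(meta$estimate),
    estimate = unname(meta$estimate), se = unname(meta$se),
    weight = unname(meta$weights)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
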