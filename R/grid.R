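#' Most conservative bounds across per-site confidence intervals
#'
#' Takes the smallest lower bound and the largest upper bound across the
#' regional confidence intervals for one parameter, so that no value any
#' site considers plausible is excluded from the shared lattice.
#'
#' @param lower,upper Numeric vectors of per-site interval endpoints
#'   (elementwise `lower < upper`).
#' @return Named numeric vector `c(lower = , upper = )`.
#' @examples
#' conservative_bounds(c(0.25, 0.31, 0.21, 0.09, 0.21),
#'                     c(0.90, 0.63, 0.53, 0.24, 0.73))  # 0.09, 0.90
#' @export
conservative_bounds <- function(lower, upper) {
  if (length(lower) == 0L) stop("need at least one interval", call. = FALSE)
  stopifnot(length(lower) == length(upper), is.numeric(lower), is.numeric(upper))
  if (any(lower >= upper)) stop("each interval must have lower < upper", call. = FALSE)
  c(lower = min(lower), upper = max(upper))
}

#' Build one uniformly spaced parameter axis
#'
#' Values are `lower + k * increment` for `k = 0 .. K` with
#' `K = floor((upper - lower) / increment + 1e-9)`: generated by integer
#' indexing from the exact (unrounded) lower anchor, never by repeated
#' addition, so axes are bit-reproducible across runs and platforms. The
#' sequence stops at the last value not exceeding `upper` (with 1e-9
#' slack for representation error); it never overshoots the declared
#' plausible range. A range narrower than one increment yields a single
#' value -- legitimate for very precisely estimated parameters.
#'
#' @param name Parameter name.
#' @param lower,upper Axis bounds, `lower < upper`.
#' @param increment Uniform spacing, `> 0`.
#' @return An object of class `fl_axis` with fields `name`, `lower`,
#'   `upper`, `increment`, `values`.
#' @examples
#' build_axis("hypertension", 0.09, 0.90, 0.01)$values  # length 82
#' @export
build_axis <- function(name, lower, upper, increment) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(increment) || increment <= 0) {
    stop("`increment` must be > 0", call. = FALSE)
  }
  if (lower >= upper) stop("axis requires lower < upper", call. = FALSE)
  K <- floor((upper - lower) / increment + 1e-9)
  values <- lower + (0:K) * increment
  structure(
    list(name = name, lower = lower, upper = upper,
         increment = increment, values = values),
    class = "fl_axis"
  )
}

#' Build the shared parameter lattice from the sites' local fits
#'
#' Round-1 coordination: for each model parameter, the most conservative
#' bounds across the sites' Wald confidence intervals define an axis,
#' segmented at a uniform increment (0.01 and 0.005 in the case study).
#' The axes are anchored at the exact, unrounded lower bounds. Every
#' site's interval is contained in its axis range by construction, so no
#' plausible parameter value is excluded from the grid search.
#'
#' The resulting `fl_grid_spec` carries a fingerprint -- a SHA-256 digest
#' of the axis names, full-precision bounds, and increment -- which is
#' how tensors from different sites are later checked for alignment
#' (never by float-comparing whole axis vectors).
#'
#' @param fits List of `fl_local_fit` objects; all must be converged and
#'   share an identical parameter set and order (the protocol's
#'   model-consistency assumption).
#' @param increment Lattice spacing, common to all axes.
#' @param level Confidence level of the intervals the bounds are drawn
#'   from (default 0.95 as in the case study).
#' @return An object of class `fl_grid_spec`: `axes` (list of
#'   `fl_axis`), `increment`, `fingerprint`.
#' @export
build_grid_spec <- function(fits, increment, level = 0.95) {
  stopifnot(length(fits) >= 1L)
  lapply(fits, function(f) stopifnot(inherits(f, "fl_local_fit")))
  params <- fits[[1L]]$parameters
  for (f in fits) {
    if (!identical(f$parameters, params)) {
      stop("site '", f$site_id, "' uses a different model structure (",
           paste(f$parameters, collapse = ", "), ") than site '",
           fits[[1L]]$site_id, "' (", paste(params, collapse = ", "),
           "); the protocol requires an identical model at every site",
           call. = FALSE)
    }
    if (!isTRUE(f$converged)) {
      stop("site '", f$site_id, "' did not converge; cannot anchor the grid",
           call. = FALSE)
    }
  }
  cis <- lapply(fits, wald_ci, level = level)
  axes <- lapply(seq_along(params), function(j) {
    b <- conservative_bounds(
      vapply(cis, function(ci) ci[j, "lower"], 0),
      vapply(cis, function(ci) ci[j, "upper"], 0)
    )
    build_axis(params[j], b[["lower"]], b[["upper"]], increment)
  })
  grid_spec(axes, increment)
}

#' Assemble a grid specification from explicit axes
#'
#' Lower-level constructor used by [build_grid_spec()] and by demo grids
#' built from other bounds; computes the alignment fingerprint.
#'
#' @param axes List of `fl_axis` objects, in model parameter order.
#' @param increment Common lattice spacing.
#' @return An `fl_grid_spec`.
#' @export
grid_spec <- function(axes, increment) {
  stopifnot(length(axes) >= 1L)
  lapply(axes, function(a) stopifnot(inherits(a, "fl_axis")))
  structure(
    list(axes = axes, increment = increment,
         fingerprint = grid_fingerprint(axes, increment)),
    class = "fl_grid_spec"
  )
}

# Canonical digest over axis names, full-precision decimal bounds and the
# increment. %.17g round-trips doubles exactly, so the fingerprint changes
# iff any name, bound or the increment changes.
grid_fingerprint <- function(axes, increment) {
  canon <- paste(
    vapply(axes, function(a) {
      sprintf("%s:%.17g:%.17g", a$name, a$lower, a$upper)
    }, ""),
    collapse = ";"
  )
  digest::digest(paste0(canon, "|inc:", sprintf("%.17g", increment)),
                 algo = "sha256", serialize = FALSE)
}

#' Number of lattice cells
#'
#' Product of the axis lengths -- the number of log-likelihood
#' evaluations each site performs in round 2. Computed in double
#' precision so counts beyond 1e9 (easily reached at fine increments)
#' do not overflow integer arithmetic.
#'
#' @param spec An `fl_grid_spec`.
#' @return A double scalar count.
#' @export
grid_size <- function(spec) {
  stopifnot(inherits(spec, "fl_grid_spec"))
  prod(vapply(spec$axes, function(a) as.double(length(a$values)), 0))
}

#' @export
print.fl_grid_spec <- function(x, ...) {
  cat("Parameter lattice: increment", format(x$increment),
      "-", format(grid_size(x), big.mark = ","), "cells\n")
  for (a in x$axes) {
    cat(sprintf("  %-14s [%g, %g] (%d values)\n",
                a$name, a$lower, a$upper, length(a$values)))
  }
  cat("  fingerprint:", substr(x$fingerprint, 1, 16), "...\n")
  invisible(x)
}

#' Serialise a grid spec (the round-1 coordinator message)
#'
#' @param spec An `fl_grid_spec`.
#' @param path Output path.
#' @return `path`, invisibly; `read_grid_spec()` returns the spec.
#' @export
write_grid_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fl_grid_spec"))
  obj <- list(
    schema = "fedlik/grid_spec/1",
    increment = spec$increment,
    # bounds additionally carried as %.17g strings: JSON number output
    # is limited to 15 significant digits, which would break the
    # bit-exact anchor (and hence the fingerprint) on round-trip
    increment_repr = sprintf("%.17g", spec$increment),
    axes = lapply(spec$axes, function(a) {
      list(name = a$name, lower = a$lower, upper = a$upper,
           lower_repr = sprintf("%.17g", a$lower),
           upper_repr = sprintf("%.17g", a$upper))
    }),
    fingerprint = spec$fingerprint
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_spec
#' @export
read_grid_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "fedlik/grid_spec/1")) {
    stop("not a fedlik grid-spec artifact: ", path, call. = FALSE)
  }
  increment <- as.numeric(obj$increment_repr)
  axes <- lapply(obj$axes, function(a) {
    build_axis(a$name, as.numeric(a$lower_repr), as.numeric(a$upper_repr),
               increment)
  })
  spec <- grid_spec(axes, increment)
  if (!identical(spec$fingerprint, obj$fingerprint)) {
    stop("grid fingerprint mismatch after reading ", path,
         "; artifact corrupted or produced by an incompatible version",
         call. = FALSE)
  }
  spec
}
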