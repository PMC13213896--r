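# Cell ordering is row-major in axis order: the LAST axis varies fastest.
# All linear indices are 0-based internally; decode_cells maps them to
# 1-based per-axis indices.
decode_cells <- function(idx0, lengths) {
  p <- length(lengths)
  out <- matrix(0L, nrow = length(idx0), ncol = p)
  rem <- idx0
  for (j in p:1) {
    out[, j] <- as.integer(rem %% lengths[j]) + 1L
    rem <- rem %/% lengths[j]
  }
  out
}

# Low-level tensor constructor; validates the value vector against the grid.
new_loglik_tensor <- function(values, grid, site_id, n_observations) {
  stopifnot(inherits(grid, "fl_grid_spec"))
  lengths <- vapply(grid$axes, function(a) length(a$values), 0L)
  if (length(values) != prod(as.double(lengths))) {
    stop("tensor has ", length(values), " values but the grid has ",
         prod(as.double(lengths)), " cells", call. = FALSE)
  }
  structure(
    list(
      grid_fingerprint = grid$fingerprint,
      axis_names = vapply(grid$axes, function(a) a$name, ""),
      axis_values = lapply(grid$axes, function(a) a$values),
      dim = lengths,
      increment = grid$increment,
      values = as.double(values),
      site_id = site_id,
      n_observations = n_observations,
      max_value = max(values)
    ),
    class = "fl_loglik_tensor"
  )
}

#' Evaluate the log-likelihood tensor over the shared lattice
#'
#' Round 2, run inside each site: the Bernoulli log-likelihood of the
#' site's data is computed at every cell of the shared lattice, i.e. at
#' every combination of candidate parameter values. Cells are processed
#' in chunks (vectorised across cells, one fixed-order pass over the
#' observations per chunk); chunking partitions cells, never
#' observations, so the result is bitwise identical for any
#' `chunk_cells`. The tensor -- aggregate-level by construction -- is
#' the only artifact the site shares in round 2.
#'
#' @param dataset An [site_dataset()].
#' @param spec An [model_spec()]; its parameter order must match the
#'   grid's axis order.
#' @param grid An `fl_grid_spec` from [build_grid_spec()].
#' @param chunk_cells Cells evaluated per chunk; default sizes chunks so
#'   a chunk's working matrix stays near 2e7 entries.
#' @param memory_limit Ceiling in bytes on the tensor allocation itself
#'   (default 2 GiB). Exceeding it is an error suggesting a coarser
#'   increment or narrower bounds.
#' @param verbose Log per-chunk progress via `message()`.
#' @return An object of class `fl_loglik_tensor`: `values` (row-major in
#'   axis order, last axis fastest), axis metadata, `grid_fingerprint`,
#'   `site_id`, `n_observations`, cached `max_value`.
#' @export
evaluate_tensor <- function(dataset, spec, grid,
                            chunk_cells = NULL,
                            memory_limit = 2 * 1024^3,
                            verbose = FALSE) {
  stopifnot(inherits(grid, "fl_grid_spec"))
  axis_names <- vapply(grid$axes, function(a) a$name, "")
  if (!identical(axis_names, spec$parameters)) {
    stop("grid axes (", paste(axis_names, collapse = ", "),
         ") do not match the model parameters (",
         paste(spec$parameters, collapse = ", "), ")", call. = FALSE)
  }
  dm <- design_matrix(dataset, spec)
  X <- dm$X
  y <- dm$y
  n <- nrow(X)
  cells <- grid_size(grid)
  if (8 * cells > memory_limit) {
    stop("lattice of ", format(cells, big.mark = ","), " cells needs ",
         round(8 * cells / 1024^3, 2), " GiB, above the ",
         round(memory_limit / 1024^3, 2), " GiB ceiling; use a coarser ",
         "increment, narrower bounds, or raise `memory_limit` for ",
         "streaming over more chunks", call. = FALSE)
  }
  if (is.null(chunk_cells)) {
    chunk_cells <- max(1024, floor(2e7 / n))
  }
  stopifnot(chunk_cells >= 1)

  lengths <- vapply(grid$axes, function(a) length(a$values), 0L)
  axis_values <- lapply(grid$axes, function(a) a$values)
  values <- numeric(cells)
  n_chunks <- ceiling(cells / chunk_cells)
  for (ci in seq_len(n_chunks)) {
    from <- (ci - 1) * chunk_cells          # 0-based first cell
    m <- min(chunk_cells, cells - from)
    coords <- decode_cells(from + seq_len(m) - 1, lengths)
    B <- vapply(seq_along(axis_values),
                function(j) axis_values[[j]][coords[, j]],
                numeric(m))
    if (m == 1L) B <- matrix(B, nrow = 1L)
    eta <- X %*% t(B)                       # n x m
    values[(from + 1):(from + m)] <-
      .colSums(y * eta - softplus(eta), n, m)
    if (verbose) {
      message("site '", dataset$site_id, "': chunk ", ci, "/", n_chunks,
              " (", m, " cells)")
    }
  }
  new_loglik_tensor(values, grid, dataset$site_id, n)
}

#' Locate the maximising lattice cell
#'
#' The cell holding the grid maximum of the log-likelihood -- the
#' lattice analogue of the maximum-likelihood estimate. Ties are broken
#' by the lowest row-major linear index (deterministic).
#'
#' @param tensor An `fl_loglik_tensor`.
#' @return List with `indices` (1-based per-axis), `beta` (named axis
#'   values at the cell), `max_loglik`.
#' @export
argmax_cell <- function(tensor) {
  stopifnot(inherits(tensor, "fl_loglik_tensor"))
  i <- which.max(tensor$values)             # first max = lowest index
  k <- decode_cells(i - 1, tensor$dim)[1L, ]
  beta <- vapply(seq_along(k), function(j) tensor$axis_values[[j]][k[j]], 0)
  names(beta) <- tensor$axis_names
  list(indices = k, beta = beta, max_loglik = tensor$values[i])
}

#' Relative-likelihood region of a tensor
#'
#' Cells where the likelihood is at least `threshold` times the maximum
#' likelihood, i.e. where the log-likelihood is within `log(threshold)`
#' of the maximum. The case-study cutoff 14.7% approximately calibrates
#' the region to a 95% confidence set for one parameter
#' (`exp(-qchisq(0.95, 1) / 2)` = 0.1465).
#'
#' @param tensor An `fl_loglik_tensor`.
#' @param threshold Relative-likelihood cutoff in (0, 1].
#' @return Logical vector over cells (row-major), `TRUE` inside the
#'   region. The argmax cell is always included.
#' @export
relative_likelihood_region <- function(tensor, threshold = 0.147) {
  stopifnot(inherits(tensor, "fl_loglik_tensor"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  tensor$values >= tensor$max_value + log(threshold)
}

#' Likelihood interval for one parameter
#'
#' Projects the relative-likelihood region onto one axis: the smallest
#' and largest axis values attained by any cell in the region. A single
#' cell gives a degenerate interval `(v, v)`, which occurs in practice
#' for very precisely estimated parameters whose axis resolves to few
#' lattice values.
#'
#' @param tensor An `fl_loglik_tensor`.
#' @param axis Axis index (1-based, model parameter order) or name.
#' @param threshold Relative-likelihood cutoff, as in
#'   [relative_likelihood_region()].
#' @return Numeric `c(lower, upper)` on the parameter scale.
#' @export
likelihood_interval <- function(tensor, axis, threshold = 0.147) {
  stopifnot(inherits(tensor, "fl_loglik_tensor"))
  if (is.character(axis)) axis <- match(axis, tensor$axis_names)
  stopifnot(is.finite(axis), axis >= 1, axis <= length(tensor$dim))
  mask <- relative_likelihood_region(tensor, threshold)
  idx0 <- which(mask) - 1
  stride <- if (axis == length(tensor$dim)) 1 else
    prod(as.double(tensor$dim[(axis + 1):length(tensor$dim)]))
  k <- (idx0 %/% stride) %% tensor$dim[axis]
  vals <- tensor$axis_values[[axis]][k + 1]
  c(lower = min(vals), upper = max(vals))
}

#' @export
print.fl_loglik_tensor <- function(x, ...) {
  am <- argmax_cell(x)
  cat("Log-likelihood tensor -- site '", x$site_id, "' (n = ",
      x$n_observations, ")\n", sep = "")
  cat("  ", paste(x$dim, collapse = " x "), " = ",
      format(length(x$values), big.mark = ","), " cells over (",
      paste(x$axis_names, collapse = ", "), ")\n", sep = "")
  cat("  max log-likelihood ", format(am$max_loglik), " at (",
      paste(signif(am$beta, 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write or read a tensor artifact
#'
#' The round-2 site-to-coordinator message: a JSON header (site id, n,
#' grid fingerprint, axis metadata, cached maximum) at `<stem>.json` and
#' the row-major cell values as little-endian 8-byte floats at
#' `<stem>.bin`. No record-level content is present by construction.
#'
#' @param tensor An `fl_loglik_tensor`.
#' @param stem Path stem; `.json` and `.bin` are appended.
#' @return `stem`, invisibly; `read_tensor()` returns the tensor.
#' @export
write_tensor <- function(tensor, stem) {
  stopifnot(inherits(tensor, "fl_loglik_tensor"))
  header <- list(
    schema = "fedlik/loglik_tensor/1",
    site_id = tensor$site_id,
    n_observations = tensor$n_observations,
    grid_fingerprint = tensor$grid_fingerprint,
    increment = tensor$increment,
    increment_repr = sprintf("%.17g", tensor$increment),
    axes = lapply(seq_along(tensor$axis_names), function(j) {
      v <- tensor$axis_values[[j]]
      list(name = tensor$axis_names[j], lower = v[1],
           upper = v[length(v)], length = length(v),
           lower_repr = sprintf("%.17g", v[1]))
    }),
    dim = as.integer(tensor$dim),
    max_value = tensor$max_value,
    payload = paste0(basename(stem), ".bin"),
    dtype = "float64-le"
  )
  jsonlite::write_json(header, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(tensor$values, con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = FALSE)
  if (!identical(header$schema, "fedlik/loglik_tensor/1")) {
    stop("not a fedlik tensor artifact: ", stem, call. = FALSE)
  }
  dim <- vapply(header$dim, as.integer, 0L)
  n_cells <- prod(as.double(dim))
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  values <- readBin(con, "double", n = n_cells, size = 8, endian = "little")
  if (length(values) != n_cells) {
    stop("tensor payload truncated: expected ", n_cells, " cells, read ",
         length(values), call. = FALSE)
  }
  increment <- as.numeric(header$increment_repr)
  axes <- lapply(header$axes, function(a) {
    # reconstruct by integer indexing from the bit-exact stored anchor
    list(name = a$name,
         values = as.numeric(a$lower_repr) +
           (0:(a$length - 1)) * increment)
  })
  structure(
    list(
      grid_fingerprint = header$grid_fingerprint,
      axis_names = vapply(axes, function(a) a$name, ""),
      axis_values = lapply(axes, function(a) a$values),
      dim = dim,
      increment = increment,
      values = values,
      site_id = header$site_id,
      n_observations = header$n_observations,
      max_value = max(values)
    ),
    class = "fl_loglik_tensor"
  )
}
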