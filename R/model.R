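#' Define a logistic-regression model shared across sites
#'
#' A model specification names the binary outcome column and the ordered
#' covariate columns entering the linear predictor. An intercept is always
#' implicit at position 0, so the parameter vector has length
#' `1 + length(covariates)`. The link is fixed at logit: the federated
#' protocol requires every site to evaluate exactly the same likelihood,
#' so the model structure is part of the shared contract and is validated
#' wherever artifacts from different sites meet.
#'
#' @param outcome Name of the binary (0/1) outcome column.
#' @param covariates Character vector of covariate column names, in design
#'   order. Must be non-empty and unique.
#' @return An object of class `fl_model_spec` with elements `outcome`,
#'   `covariates` and `parameters` (`"(Intercept)"` followed by the
#'   covariate names).
#' @examples
#' model_spec("ckd", c("hypertension", "sex", "age"))
#' @export
model_spec <- function(outcome, covariates) {
  stopifnot(is.character(outcome), length(outcome) == 1L, nzchar(outcome))
  if (!is.character(covariates) || length(covariates) == 0L) {
    stop("`covariates` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(covariates)) {
    stop("covariate names must be unique", call. = FALSE)
  }
  structure(
    list(
      outcome = outcome,
      covariates = covariates,
      parameters = c("(Intercept)", covariates)
    ),
    class = "fl_model_spec"
  )
}

#' Case-study model: chronic kidney disease given hypertension, sex, age
#'
#' The default specification used throughout the package: CKD onset as the
#' outcome, hypertension as the primary exposure, with sex and age as
#' confounders (four parameters including the intercept).
#'
#' @return An `fl_model_spec`.
#' @export
default_model_spec <- function() {
  model_spec("ckd", c("hypertension", "sex", "age"))
}

#' @export
print.fl_model_spec <- function(x, ...) {
  cat("Logistic model spec:", x$outcome, "~",
      paste(x$covariates, collapse = " + "), "\n")
  invisible(x)
}

#' Wrap one jurisdiction's patient-level records
#'
#' A site dataset is a plain data frame of complete records plus a site
#' identifier. The federated method assumes complete cases and an
#' identical model structure at every site, so validation is strict:
#' missing values or a non-binary outcome are errors, not warnings.
#'
#' @param data Data frame of patient-level records.
#' @param site_id Character scalar identifying the jurisdiction.
#' @return An object of class `fl_site_dataset`.
#' @export
site_dataset <- function(data, site_id) {
  stopifnot(is.data.frame(data), is.character(site_id), length(site_id) == 1L)
  if (nrow(data) < 1L) stop("site dataset must contain at least one record", call. = FALSE)
  structure(
    list(site_id = site_id, data = as.data.frame(data), n = nrow(data)),
    class = "fl_site_dataset"
  )
}

#' @export
print.fl_site_dataset <- function(x, ...) {
  cat("Site dataset '", x$site_id, "': ", x$n, " records, columns: ",
      paste(names(x$data), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Design matrix (intercept first) and outcome vector for a dataset under a
# spec; the single validation chokepoint for the complete-records /
# binary-outcome preconditions.
design_matrix <- function(dataset, spec) {
  stopifnot(inherits(dataset, "fl_site_dataset"), inherits(spec, "fl_model_spec"))
  df <- dataset$data
  missing_cols <- setdiff(c(spec$outcome, spec$covariates), names(df))
  if (length(missing_cols)) {
    stop("site '", dataset$site_id, "' is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- df[[spec$outcome]]
  if (anyNA(df[c(spec$outcome, spec$covariates)])) {
    stop("site '", dataset$site_id,
         "' contains missing values; the method assumes complete records",
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("outcome '", spec$outcome, "' must be coded 0/1", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(df[spec$covariates]))
  if (!is.numeric(X)) stop("covariates must be numeric", call. = FALSE)
  storage.mode(X) <- "double"
  list(X = X, y = as.double(y))
}

#' Read or write site data as CSV
#'
#' Round 0 of the protocol: each site holds its records as a CSV with a
#' header row; binary columns are coded 0/1. These files never leave the
#' site -- only model artifacts derived from them do.
#'
#' @param path File path.
#' @param site_id Site identifier; defaults to the file name without
#'   extension.
#' @return `read_site_csv()` returns an `fl_site_dataset`;
#'   `write_site_csv()` returns `path` invisibly.
#' @export
read_site_csv <- function(path, site_id = NULL) {
  if (is.null(site_id)) {
    site_id <- sub("\\.[^.]*$", "", basename(path))
  }
  site_dataset(utils::read.csv(path), site_id)
}

#' @rdname read_site_csv
#' @param dataset An `fl_site_dataset`.
#' @export
write_site_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "fl_site_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE)
  invisible(path)
}
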