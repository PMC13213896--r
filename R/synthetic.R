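#' Configure one synthetic site population
#'
#' Describes the covariate marginals of one jurisdiction: sample size,
#' exposure (hypertension) prevalence, proportion male, and the age
#' distribution (normal, truncated to `age_bounds`, rounded to whole
#' years -- ages in the emulated registry are visit year minus birth
#' year, hence integers).
#'
#' @param site_id Site label.
#' @param n Number of patients, `>= 1`.
#' @param exposure_prevalence,male_proportion Proportions in (0, 1).
#' @param age_mean,age_sd Age distribution in years before truncation.
#' @param age_bounds Length-2 `c(min, max)` in years.
#' @return An object of class `fl_site_config`.
#' @export
site_config <- function(site_id, n, exposure_prevalence, male_proportion,
                        age_mean = 63.38, age_sd = 12.22,
                        age_bounds = c(18, 104)) {
  stopifnot(n >= 1,
            exposure_prevalence > 0, exposure_prevalence < 1,
            male_proportion > 0, male_proportion < 1,
            length(age_bounds) == 2L, age_bounds[1] < age_bounds[2])
  structure(
    list(site_id = site_id, n = as.integer(n),
         exposure_prevalence = exposure_prevalence,
         male_proportion = male_proportion,
         age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds),
    class = "fl_site_config"
  )
}

#' Default five-site network emulating the pan-Canadian diabetes cohort
#'
#' Site sizes, hypertension prevalences, sex splits and age
#' distributions mirror the case study's five regions (British
#' Columbia, Alberta, Manitoba, Ontario, Maritimes; 42,341 patients in
#' total). The default generating coefficients are the case study's
#' global-model estimates, giving an overall outcome (CKD) prevalence
#' near 15%.
#'
#' @param seed Master seed; per-site substreams are derived from it and
#'   the site id, so site outputs are order-insensitive and adding a
#'   site never perturbs existing sites.
#' @param coefficients Generating log-odds coefficients
#'   `(intercept, exposure, sex, age)`.
#' @param size_factor Multiplier on the site sizes (e.g. `0.1` for a
#'   tenth-scale network); sizes are rounded.
#' @return An object of class `fl_network_config`.
#' @export
default_network_config <- function(seed = 1L,
                                   coefficients = c(-7.0460, 0.2542,
                                                    -0.0737, 0.0770),
                                   size_factor = 1) {
  sizes <- round(c(1700, 8002, 6089, 23946, 2604) * size_factor)
  sites <- list(
    site_config("british_columbia", sizes[1], 0.59, 0.54, 63.14, 12.39),
    site_config("alberta",          sizes[2], 0.62, 0.54, 62.66, 12.11),
    site_config("manitoba",         sizes[3], 0.52, 0.55, 63.03, 12.60),
    site_config("ontario",          sizes[4], 0.44, 0.53, 63.58, 12.09),
    site_config("maritimes",        sizes[5], 0.67, 0.51, 64.72, 12.08)
  )
  network_config(sites, coefficients, seed)
}

#' Assemble a network configuration
#'
#' @param sites List of [site_config()] objects.
#' @param coefficients Common generating coefficients
#'   `(intercept, exposure, sex, age)` on the log-odds scale.
#' @param seed Master seed (integer).
#' @return An `fl_network_config`.
#' @export
network_config <- function(sites, coefficients, seed = 1L) {
  stopifnot(length(sites) >= 1L, is.numeric(coefficients),
            length(coefficients) == 4L)
  lapply(sites, function(s) stopifnot(inherits(s, "fl_site_config")))
  ids <- vapply(sites, function(s) s$site_id, "")
  if (anyDuplicated(ids)) stop("site ids must be unique", call. = FALSE)
  structure(
    list(sites = sites, coefficients = coefficients,
         seed = as.integer(seed)),
    class = "fl_network_config"
  )
}

# Deterministic per-site substream seed: a polynomial hash of the site id
# mixed with the master seed, kept below 2^31. Depending on the id (not
# the position) makes generation order-insensitive.
site_seed <- function(master_seed, site_id) {
  h <- 0
  for (ch in utf8ToInt(site_id)) h <- (h * 31 + ch) %% 2147480017
  as.integer((abs(as.double(master_seed)) %% 97861 * 21701 + h) %% 2147483629)
}

#' Generate one synthetic site
#'
#' Covariates are drawn independently (the emulated registry publishes
#' only marginals): exposure and sex as Bernoulli, age as a truncated
#' normal (inverse-CDF sampling) rounded to whole years. The binary
#' outcome is Bernoulli with success probability
#' `plogis(b0 + b1*exposure + b2*sex + b3*age)`. Sex is coded male = 1.
#' Fixed seed implies bit-identical output.
#'
#' @param config An [site_config()].
#' @param coefficients `(intercept, exposure, sex, age)` log-odds
#'   coefficients.
#' @param seed Integer seed for this site's stream.
#' @return An [site_dataset()] with columns `ckd`, `hypertension`,
#'   `sex`, `age`.
#' @export
generate_site <- function(config, coefficients, seed) {
  stopifnot(inherits(config, "fl_site_config"), length(coefficients) == 4L)
  set.seed(as.integer(seed))
  n <- config$n
  lo <- stats::pnorm(config$age_bounds[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_bounds[2], config$age_mean, config$age_sd)
  age <- round(stats::qnorm(stats::runif(n, lo, hi),
                            config$age_mean, config$age_sd))
  sex <- stats::rbinom(n, 1L, config$male_proportion)
  exposure <- stats::rbinom(n, 1L, config$exposure_prevalence)
  eta <- coefficients[1] + coefficients[2] * exposure +
    coefficients[3] * sex + coefficients[4] * age
  outcome <- stats::rbinom(n, 1L, stats::plogis(eta))
  site_dataset(
    data.frame(ckd = outcome, hypertension = exposure, sex = sex, age = age),
    config$site_id
  )
}

#' Generate every site of a network
#'
#' Each site is drawn from its own substream (see [site_config()] and
#' `site_seed`), so permuting the site order, or adding sites, leaves
#' the other sites' data bit-identical.
#'
#' @param config An [network_config()].
#' @return Named list of [site_dataset()] objects, one per site.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "fl_network_config"))
  out <- lapply(config$sites, function(s) {
    generate_site(s, config$coefficients, site_seed(config$seed, s$site_id))
  })
  stats::setNames(out, vapply(config$sites, function(s) s$site_id, ""))
}

#' Generate a network with site-specific exposure effects
#'
#' Same generative model as [generate_network()] except the exposure
#' coefficient varies by site while intercept, sex and age effects stay
#' common -- the scenario used to demonstrate violation of the
#' common-effect assumption (inflated Cochran's Q and I-squared).
#' With all per-site values equal to the common coefficient the output
#' is identical to [generate_network()].
#'
#' @param config An [network_config()].
#' @param per_site_exposure_betas One exposure coefficient per site, in
#'   site order.
#' @return Named list of [site_dataset()] objects.
#' @export
heterogeneous_network <- function(config, per_site_exposure_betas) {
  stopifnot(inherits(config, "fl_network_config"))
  if (length(per_site_exposure_betas) != length(config$sites)) {
    stop("need exactly one exposure coefficient per site (",
         length(config$sites), " sites, got ",
         length(per_site_exposure_betas), ")", call. = FALSE)
  }
  out <- lapply(seq_along(config$sites), function(i) {
    s <- config$sites[[i]]
    beta <- config$coefficients
    beta[2] <- per_site_exposure_betas[i]
    generate_site(s, beta, site_seed(config$seed, s$site_id))
  })
  stats::setNames(out, vapply(config$sites, function(s) s$site_id, ""))
}

#' Write a generated network to per-site CSVs plus a manifest
#'
#' @param datasets Named list of [site_dataset()] objects.
#' @param config The [network_config()] that produced them.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_network <- function(datasets, config, dir) {
  stopifnot(inherits(config, "fl_network_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in datasets) {
    write_site_csv(d, file.path(dir, paste0(d$site_id, ".csv")))
  }
  manifest <- list(
    schema = "fedlik/network_manifest/1",
    seed = config$seed,
    coefficients = config$coefficients,
    sites = lapply(config$sites, function(s) {
      list(site_id = s$site_id, n = s$n,
           exposure_prevalence = s$exposure_prevalence,
           male_proportion = s$male_proportion,
           age_mean = s$age_mean, age_sd = s$age_sd,
           age_bounds = s$age_bounds,
           file = paste0(s$site_id, ".csv"))
    })
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Concatenate site datasets into the pooled (global) dataset
#'
#' The benchmark the federated method is judged against: in the real
#' setting this pooling is impossible, but for synthetic networks it
#' defines the gold-standard global fit.
#'
#' @param datasets List of [site_dataset()] objects.
#' @param site_id Label for the pooled dataset.
#' @return An [site_dataset()].
#' @export
pool_datasets <- function(datasets, site_id = "global") {
  stopifnot(length(datasets) >= 1L)
  lapply(datasets, function(d) stopifnot(inherits(d, "fl_site_dataset")))
  site_dataset(do.call(rbind, lapply(datasets, function(d) d$data)), site_id)
}
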