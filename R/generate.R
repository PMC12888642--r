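#' Specification of one synthetic site
#'
#' @param site_id short site label.
#' @param n target sample count (>= 1).
#' @param incidence target positive-class fraction in `[0, 1]`.
#' @param site_shift scalar covariate-shift offset for this site: each binary
#'   feature's rate is moved by `site_shift` on the logit scale and each
#'   continuous feature's mean by `site_shift` on the raw scale. Between-site
#'   heterogeneity enters through this shift (the label-model intercept is
#'   calibrated away to hit `incidence`, so a plain intercept offset would be
#'   absorbed).
#' @return an object of class `site_spec`.
#' @export
site_spec <- function(site_id, n, incidence, site_shift = 0) {
  stopifnot(
    is.character(site_id), length(site_id) == 1L,
    is.numeric(n), length(n) == 1L, is.finite(n), n >= 1,
    is.numeric(incidence), length(incidence) == 1L, is.finite(incidence),
    incidence >= 0, incidence <= 1,
    is.numeric(site_shift), length(site_shift) == 1L, is.finite(site_shift)
  )
  structure(
    list(site_id = site_id, n = as.integer(n), incidence = incidence,
         site_shift = site_shift),
    class = "site_spec"
  )
}

#' Published eleven-hospital delirium cohort profile
#'
#' Per-site sample counts and delirium (positive-class) counts of the
#' eleven-hospital delirium cohort that the synthetic generator
#' emulates: 29,479 patients in total, 8,900 of them delirium cases, with
#' per-site incidence ranging from 11.4% to 63.4%.
#'
#' @return data.frame with columns `site_id`, `n`, `positives`.
#' @examples
#' prof <- delirium_site_profile()
#' sum(prof$n)  # 29479
#' @export
delirium_site_profile <- function() {
  data.frame(
    site_id = sprintf("H%02d", 1:11),
    n = c(5033L, 4368L, 1918L, 2904L, 2160L, 1271L, 552L, 1873L, 2036L,
          6624L, 740L),
    positives = c(953L, 1000L, 390L, 408L, 385L, 287L, 160L, 628L, 408L,
                  4197L, 84L),
    stringsAsFactors = FALSE
  )
}

#' Default latent effect sizes for the synthetic generator
#'
#' Log-odds coefficients over `d_binary + d_continuous` features: ten binary
#' and four continuous features carry signal of mixed sign and decaying
#' magnitude (|beta| 0.25-0.9, roughly the strength of strong EMR risk
#' factors); the rest are noise features. Shared across sites.
#'
#' @param d_binary,d_continuous feature counts.
#' @return numeric vector of length `d_binary + d_continuous`.
#' @export
default_effect_sizes <- function(d_binary = 30L, d_continuous = 10L) {
  beta_bin <- c(0.9, -0.7, 0.6, 0.6, -0.5, 0.5, -0.4, 0.4, 0.3, -0.3)
  beta_con <- c(0.5, -0.4, 0.3, 0.25)
  c(rep_len(c(beta_bin, rep(0, max(0L, d_binary - length(beta_bin)))), d_binary),
    rep_len(c(beta_con, rep(0, max(0L, d_continuous - length(beta_con)))), d_continuous))
}

#' Configuration of the synthetic multi-site cohort generator
#'
#' @param specs list of [site_spec()] objects (one synthetic site each).
#'   Defaults to the [delirium_site_profile()] sizes and incidences, with
#'   site shifts evenly spaced in `[-0.3, 0.3]`.
#' @param d_binary,d_continuous number of binary / continuous features.
#' @param effect_sizes log-odds coefficient vector of length
#'   `d_binary + d_continuous`, shared by all sites.
#' @param noise_sd standard deviation of the latent per-sample logit noise.
#' @param seed integer master seed; fully determines the generated cohort.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(specs = NULL,
                             d_binary = 30L,
                             d_continuous = 10L,
                             effect_sizes = default_effect_sizes(d_binary, d_continuous),
                             noise_sd = 0.5,
                             seed = 1L) {
  if (is.null(specs)) {
    prof <- delirium_site_profile()
    shifts <- seq(-0.3, 0.3, length.out = nrow(prof))
    specs <- lapply(seq_len(nrow(prof)), function(i) {
      site_spec(prof$site_id[i], prof$n[i], prof$positives[i] / prof$n[i],
                site_shift = shifts[i])
    })
  }
  stopifnot(is.list(specs), length(specs) >= 1L)
  if (!all(vapply(specs, inherits, logical(1), "site_spec"))) {
    stop("`specs` must be a list of site_spec objects")
  }
  d_binary <- as.integer(d_binary); d_continuous <- as.integer(d_continuous)
  if (d_binary + d_continuous < 1L) stop("at least one feature is required")
  if (!is.numeric(effect_sizes) || length(effect_sizes) != d_binary + d_continuous ||
      !all(is.finite(effect_sizes))) {
    stop("`effect_sizes` must be a finite numeric vector of length d_binary + d_continuous")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || !is.finite(noise_sd) ||
      noise_sd < 0) {
    stop("`noise_sd` must be a finite nonnegative scalar")
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(
    list(specs = specs, d_binary = d_binary, d_continuous = d_continuous,
         effect_sizes = effect_sizes, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Bisection on the site intercept b so that mean(sigmoid(eta + b)) hits the
# target incidence for this site's realized linear predictors.
#' @keywords internal
calibrate_intercept <- function(eta, target, tol = 1e-10) {
  lo <- -40; hi <- 40
  f <- function(b) mean(sigmoid(eta + b)) - target
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic federated cohort
#'
#' Draws one [site_cohort()] per [site_spec()] from a logistic latent model:
#' binary features are Bernoulli with per-feature rates (drawn once from
#' U(0.05, 0.5), shared across sites, shifted on the logit scale by each
#' site's `site_shift`), continuous features are Normal with mean
#' `site_shift` and unit variance, and labels follow
#' `P(y = 1 | x) = sigmoid(beta' x + b_site + eps)`, `eps ~ N(0, noise_sd)`,
#' with the site intercept `b_site` calibrated by bisection so that the mean
#' predicted probability equals the site's target incidence. The signal
#' `beta` is shared by all sites (horizontal setting). The master seed fully
#' determines the output.
#'
#' @param config a [generator_config()].
#' @return a [federated_cohort()] (or a single `site_cohort` when `config`
#'   has exactly one spec).
#' @examples
#' cfg <- generator_config(
#'   specs = list(site_spec("A", 200, 0.3), site_spec("B", 150, 0.5)),
#'   d_binary = 6, d_continuous = 2, seed = 7
#' )
#' generate_federated_cohort(cfg)
#' @export
generate_federated_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  d <- config$d_binary + config$d_continuous
  n_sites <- length(config$specs)
  # fixed-size seed block: 1 for shared rates + 3 per site (features, noise, labels)
  seeds <- derive_seeds(config$seed, 1L + 3L * n_sites)
  set.seed(seeds[1L])
  base_rates <- stats::runif(config$d_binary, 0.05, 0.5)
  fnames <- c(sprintf("b%02d", seq_len(config$d_binary)),
              sprintf("c%02d", seq_len(config$d_continuous)))
  if (config$d_binary == 0L) fnames <- sprintf("c%02d", seq_len(config$d_continuous))
  schema <- feature_schema(
    fnames,
    c(rep("binary", config$d_binary), rep("continuous", config$d_continuous))
  )

  sites <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    spec <- config$specs[[i]]
    s <- seeds[1L + 3L * (i - 1L) + 1:3]
    set.seed(s[1L])
    rates <- sigmoid(stats::qlogis(base_rates) + spec$site_shift)
    xb <- matrix(stats::rbinom(spec$n * config$d_binary, 1L,
                               rep(rates, each = spec$n)),
                 nrow = spec$n)
    xc <- matrix(stats::rnorm(spec$n * config$d_continuous,
                              mean = spec$site_shift, sd = 1),
                 nrow = spec$n)
    x <- cbind(xb, xc)
    colnames(x) <- fnames
    set.seed(s[2L])
    eps <- stats::rnorm(spec$n, 0, config$noise_sd)
    eta <- drop(x %*% config$effect_sizes) + eps
    set.seed(s[3L])
    if (spec$incidence %in% c(0, 1)) {
      warning(sprintf("site %s has degenerate incidence %g: single-class labels",
                      spec$site_id, spec$incidence))
      y <- rep(as.integer(spec$incidence), spec$n)
    } else {
      b <- calibrate_intercept(eta, spec$incidence)
      y <- stats::rbinom(spec$n, 1L, sigmoid(eta + b))
    }
    sites[[i]] <- site_cohort(spec$site_id, as.data.frame(x), y, schema = schema)
  }
  if (n_sites == 1L) return(sites[[1L]])
  federated_cohort(sites, schema = schema)
}
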