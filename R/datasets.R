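# Bundled worked datasets and synthetic-data generators.

#' Load a bundled dataset
#'
#' Three small classics used throughout the package's examples and tests:
#' \describe{
#'   \item{rat_tumor}{70 historical binomial studies of endometrial stromal
#'     polyp incidence in female rats: (y, n) pairs.}
#'   \item{navy_shipyard}{5 lots of welding material, 5 units each, with
#'     defect counts (0, 0, 0, 1, 5).}
#'   \item{insurance_counts}{One year of automobile insurance claims: the
#'     number of policyholders making y = 0..7 claims
#'     (7840, 1317, 239, 42, 14, 4, 4, 1).  Expanded to an individual-level
#'     Poisson count vector; the frequency table is kept alongside.}
#' }
#'
#' @param name Dataset name.
#' @return A list with \code{y}, \code{exposure} (or \code{NULL}), \code{k},
#'   \code{family}; for \code{insurance_counts} also \code{counts} and
#'   \code{values}.
#' @export
load_dataset <- function(name = c("rat_tumor", "navy_shipyard", "insurance_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "dspriors")
  if (path == "") stop("bundled dataset not found: ", name)
  df <- utils::read.csv(path)
  switch(name,
    rat_tumor = list(y = df$y, exposure = df$n, k = nrow(df), family = "binomial"),
    navy_shipyard = list(y = df$y, exposure = df$n, k = nrow(df), family = "binomial"),
    insurance_counts = {
      y <- rep(df$claims, df$count)
      list(y = y, exposure = NULL, k = length(y), family = "poisson",
           counts = df$count, values = df$claims)
    })
}

#' Simulate study data from a DS prior
#'
#' Draws latent parameters from the prior with [ds_sample()] and
#' observations from the family likelihood.
#'
#' @param prior A [ds_prior()] object.
#' @param k Number of studies.
#' @param exposure Trials / standard errors, recycled to length \code{k};
#'   required for binomial and normal families.
#' @param seed Optional integer seed.
#' @return A list with \code{y}, \code{exposure}, \code{theta}.
#' @export
simulate_ds <- function(prior, k, exposure = NULL, seed = NULL) {
  stopifnot(inherits(prior, "ds_prior"))
  if (!is.null(seed)) set.seed(seed)
  theta <- ds_sample(prior, k)
  fam <- prior$family$family
  if (fam %in% c("binomial", "normal")) {
    if (is.null(exposure)) stop(fam, " simulation needs exposures")
    exposure <- rep(exposure, length.out = k)
  } else exposure <- NULL
  y <- switch(fam,
    binomial = stats::rbinom(k, exposure, theta),
    poisson = stats::rpois(k, theta),
    normal = stats::rnorm(k, theta, exposure),
    exponential = stats::rexp(k, rate = theta))
  list(y = y, exposure = exposure, theta = theta)
}

#' Two-component beta-mixture simulation of prior-data conflict
#'
#' Emulates a drug-development scenario: historical control rates follow
#' \eqn{\pi(\theta) = \eta\,\mathrm{Beta}(5,45) + (1-\eta)\,\mathrm{Beta}(30,70)},
#' while the new study is generated at a fixed response rate
#' \eqn{y_{new} \sim \mathrm{Bin}(n_{new}, p_{new})}.  Increasing \eqn{\eta}
#' injects heterogeneity into the historical studies and sharpens the
#' conflict between prior and new data.  Each replicate fits the DS model to
#' the historical studies and scores three estimates of the new study's rate
#' -- the sample proportion, the Stein PEB mean, and the Elastic-Bayes mean
#' -- against the generative truth \code{p_new}.
#'
#' @param eta Mixture weight of the low-rate component, in \eqn{[0, 1]}.
#' @param k Number of historical studies per replicate (default 100).
#' @param n_trials Trials per historical study (default 60).
#' @param n_new Trials for the new study (default 50).
#' @param p_new True rate of the new study (default 0.3).
#' @param reps Number of replicates (default 250).
#' @param seed Integer seed.
#' @param m_max Basis order for the fits.
#' @return A list with \code{eta}, the per-replicate \code{estimates} data
#'   frame and the \code{mse} vector (\code{mle}, \code{peb}, \code{ds}).
#' @export
simulate_pharma <- function(eta, k = 100, n_trials = 60, n_new = 50,
                            p_new = 0.3, reps = 250, seed = 1, m_max = 8) {
  if (eta < 0 || eta > 1) stop("'eta' must lie in [0, 1]")
  set.seed(seed)
  out <- matrix(NA_real_, reps, 3, dimnames = list(NULL, c("mle", "peb", "ds")))
  for (r in seq_len(reps)) {
    low <- stats::runif(k) < eta
    theta <- ifelse(low, stats::rbeta(k, 5, 45), stats::rbeta(k, 30, 70))
    y <- stats::rbinom(k, n_trials, theta)
    y_new <- stats::rbinom(1, n_new, p_new)
    fit <- tryCatch(
      ds_fit(y, n_trials, "binomial", start = "mle", m_max = m_max),
      error = function(e) NULL)
    if (is.null(fit)) next
    out[r, "mle"] <- y_new / n_new
    out[r, "peb"] <- stein_peb(y_new, n_new, fit$family)
    out[r, "ds"] <- elastic_bayes(y_new, n_new, fit$prior)
  }
  ok <- stats::complete.cases(out)
  mse <- colMeans((out[ok, , drop = FALSE] - p_new)^2)
  list(eta = eta, estimates = as.data.frame(out[ok, , drop = FALSE]),
       mse = mse, reps_used = sum(ok))
}
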