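# Inference layer: LP marginal/posterior/expectation machinery,
# Stein parametric EB, Elastic-Bayes, Robbins' rule, micro and macro
# summaries.

#' LP marginal density
#'
#' Marginal of one observation under the DS prior:
#' \eqn{f_{LP}(y) = f_G(y)\,(1 + \sum_j c_j E_G[T_j|y])}.
#'
#' @inheritParams marginal_g
#' @param prior A [ds_prior()] object.
#' @return Marginal density value; a warning is raised if a pathological
#'   coefficient vector drives it negative.
#' @export
marginal_lp <- function(y, exposure = NULL, prior) {
  stopifnot(inherits(prior, "ds_prior"), length(y) == 1L)
  fG <- marginal_g(y, exposure, prior$family)
  if (prior$m == 0) return(fG)
  pe <- post_expectations(y, exposure, prior$family, prior$m)
  out <- fG * (1 + sum(prior$coef * pe$ET))
  if (out < 0) warning("negative LP marginal; coefficient vector is outside the valid region")
  unname(out)
}

#' LP posterior density
#'
#' Closed-form posterior under the DS prior:
#' \deqn{\pi_{LP}(\theta|y) = \pi_G(\theta|y)\,
#'   \frac{1 + \sum_j c_j T_j(\theta;G)}{1 + \sum_j c_j E_G[T_j|y]}.}
#'
#' @param theta Evaluation points.
#' @inheritParams marginal_lp
#' @export
posterior_lp <- function(theta, y, exposure = NULL, prior) {
  stopifnot(inherits(prior, "ds_prior"), length(y) == 1L)
  fam <- prior$family
  check_support(fam, theta)
  pp <- posterior_g(y, validate_obs(fam, y, exposure), fam)
  base <- post_density(pp, theta)
  if (prior$m == 0) return(base)
  pe <- post_expectations(y, exposure, fam, prior$m)
  denom <- 1 + sum(prior$coef * pe$ET)
  if (abs(denom) < 1e-12) stop("degenerate prior-data pair: zero normalising constant")
  d <- u_function(g_cdf(fam, theta), prior)
  base * d / denom
}

#' LP posterior expectation (Bayes rule in ratio form)
#'
#' \eqn{E_{LP}[h(\Theta)|y]} computed from the conjugate building blocks:
#' \deqn{\frac{E_G[h|y] + \sum_j c_j E_G[h\,T_j|y]}{1 + \sum_j c_j E_G[T_j|y]}.}
#' With \eqn{h \equiv 1} the ratio is exactly 1 (normalisation).
#'
#' @param h Function of theta, vectorised.
#' @inheritParams marginal_lp
#' @export
posterior_mean_lp <- function(h = identity, y, exposure = NULL, prior) {
  stopifnot(inherits(prior, "ds_prior"), length(y) == 1L)
  fam <- prior$family
  exposure <- validate_obs(fam, y, exposure)
  pp <- posterior_g(y, exposure, fam)
  gq <- gauss_nodes(128)
  theta <- post_quantile(pp, gq$x)
  hv <- h(theta)
  Eh <- sum(gq$w * hv)
  if (prior$m == 0) return(Eh)
  L <- leg_matrix(g_cdf(fam, theta), prior$m)
  EhT <- as.vector(crossprod(L, gq$w * hv))
  ET <- as.vector(crossprod(L, gq$w))
  denom <- 1 + sum(prior$coef * ET)
  if (abs(denom) < 1e-12) stop("degenerate prior-data pair: zero normalising constant")
  (Eh + sum(prior$coef * EhT)) / denom
}

#' Stein parametric empirical-Bayes estimate
#'
#' The conjugate posterior mean in shrinkage form: a weighted average of the
#' study estimate and the prior mean (binomial
#' \eqn{\check\theta = \frac{n}{\alpha+\beta+n}\tilde\theta +
#' \frac{\alpha+\beta}{\alpha+\beta+n}\frac{\alpha}{\alpha+\beta}};
#' Poisson \eqn{(y+\alpha)/(\beta^{-1}+1)}; normal
#' \eqn{\lambda\mu + (1-\lambda)y}).
#'
#' @inheritParams marginal_g
#' @return Posterior mean(s) under the conjugate prior; vectorised.
#' @export
stein_peb <- function(y, exposure = NULL, family) {
  stopifnot(inherits(family, "conj_family"))
  exposure <- validate_obs(family, y, exposure)
  h <- family$hyper
  switch(family$family,
    binomial = unname((h["alpha"] + y) / (h["alpha"] + h["beta"] + exposure)),
    poisson = unname((y + h["alpha"]) / (1 / h["beta"] + 1)),
    normal = {
      lam <- exposure^2 / (exposure^2 + h["tau2"])
      unname(lam * h["mu"] + (1 - lam) * y)
    },
    exponential = unname((h["alpha"] + 1) * h["beta"] / (1 + h["beta"] * y)))
}

#' Elastic-Bayes estimate
#'
#' The LP-corrected posterior mean
#' \deqn{\hat\theta = \frac{\check\theta + \sum_j c_j E_G[\Theta T_j|y]}
#'  {1 + \sum_j c_j E_G[T_j|y]},}
#' which shrinks each study toward the relevant mode of the corrected prior
#' rather than the single grand mean.  Reduces exactly to [stein_peb()]
#' when all coefficients are zero.
#'
#' @inheritParams marginal_lp
#' @export
elastic_bayes <- function(y, exposure = NULL, prior) {
  stopifnot(inherits(prior, "ds_prior"))
  if (prior$m == 0) return(stein_peb(y, exposure, prior$family))
  posterior_mean_lp(identity, y, exposure, prior)
}

#' Robbins' frequency-ratio estimator for Poisson counts
#'
#' The prior-free empirical Bayes rule \eqn{(y+1)\,N_{y+1}/N_y}, with the
#' empirical frequencies substituted for the marginal.  Returns 0 when
#' \eqn{N_{y+1} = 0}, and \code{NA} (undefined) when \eqn{N_y = 0} or when
#' \eqn{y+1} falls outside the frequency table.
#'
#' @param y Count value(s) at which to evaluate.
#' @param counts Frequency table: number of observations with each count
#'   value in \code{values}.
#' @param values Count values corresponding to \code{counts} (default
#'   \code{0:(length(counts)-1)}).
#' @return Estimate(s); \code{NA} where undefined.
#' @examples
#' d <- load_dataset("insurance_counts")
#' robbins(0:7, d$counts)
#' @export
robbins <- function(y, counts, values = seq_along(counts) - 1) {
  if (any(counts < 0)) stop("counts must be non-negative")
  vapply(y, function(yy) {
    i <- match(yy, values)
    j <- match(yy + 1, values)
    if (is.na(i) || is.na(j)) return(NA_real_)
    if (counts[i] == 0) return(NA_real_)
    (yy + 1) * counts[j] / counts[i]
  }, numeric(1))
}

# ---- micro-inference on the model grid -------------------------------------

# Support grid for posterior summaries.  The grid is uniform in theta,
# trimmed by one grid step at endpoints where the conjugate density is
# unbounded; for the count families it spans [0, theta_max], where
# theta_max defaults to the largest observed count.  Posterior integrals
# are evaluated on the u-image of this grid with the resampled-Simpson rule
# -- the same numerical convention the coefficient estimates are calibrated
# against (methods vignette).
micro_grid <- function(fam, grid_size, theta_max = NULL) {
  h <- fam$hyper
  switch(fam$family,
    binomial = {
      lo <- if (h["alpha"] < 1) 1 / grid_size else 0
      hi <- if (h["beta"] < 1) 1 - 1 / grid_size else 1
      seq(lo, hi, length.out = grid_size)
    },
    normal = seq(h["mu"] - 3 * sqrt(h["tau2"]), h["mu"] + 3 * sqrt(h["tau2"]),
                 length.out = grid_size),
    {
      if (is.null(theta_max)) theta_max <- g_quantile(fam, 1 - 1e-6)
      lo <- if (h["alpha"] < 1) 1 / grid_size else 0
      seq(lo, theta_max, length.out = grid_size)
    })
}

#' Posterior summaries for one study under a DS prior
#'
#' Computes the frequentist estimate, the Stein PEB mean, and the DS
#' posterior mean, median and mode on the model's support grid.
#'
#' @param object A [ds_fit()] or [ds_prior()] object.
#' @param y Observation.
#' @param exposure Trials / standard error, as the family requires.
#' @param grid_size Support-grid resolution (default 1000).
#' @param theta_max Upper limit of the count-parameter grid; defaults to the
#'   largest count in the fitted data (fit objects) or a high prior
#'   quantile.
#' @return A list with \code{mle}, \code{peb_mean}, \code{ds_mean},
#'   \code{ds_median}, \code{ds_mode}.
#' @export
ds_micro <- function(object, y, exposure = NULL, grid_size = 1000, theta_max = NULL) {
  prior <- if (inherits(object, "ds_fit")) object$prior else object
  stopifnot(inherits(prior, "ds_prior"))
  fam <- prior$family
  exposure <- validate_obs(fam, y, exposure)
  if (is.null(theta_max) && inherits(object, "ds_fit") &&
      fam$family %in% c("poisson", "exponential")) {
    theta_max <- max(object$data$y, y)
  }
  pp <- posterior_g(y, exposure, fam)
  mle <- switch(fam$family,
    binomial = y / exposure,
    poisson = y,
    normal = y,
    exponential = 1 / y)
  peb <- post_mean_closed(pp)

  theta <- micro_grid(fam, grid_size, theta_max)
  u <- g_cdf(fam, theta)
  w <- suppressWarnings(post_density(pp, theta) / g_density(fam, theta))
  w[!is.finite(w)] <- 0
  d <- u_function(u, prior)
  dw <- d * w
  denom <- simpson_interp(u, dw)
  if (!is.finite(denom) || abs(denom) < 1e-300)
    stop("degenerate posterior normalisation on the support grid")
  ds_mean <- simpson_interp(u, theta * dw) / denom

  # posterior density on the theta grid (for median and mode)
  dens <- post_density(pp, theta) * pmax(d, 0)
  z <- trapezoid(theta, dens)
  cdf <- c(0, cumsum(diff(theta) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2)) / z
  ds_median <- stats::approx(cdf, theta, xout = 0.5, ties = "ordered")$y

  i_max <- which.max(dens)
  lo <- theta[max(1, i_max - 1)]; hi <- theta[min(length(theta), i_max + 1)]
  f <- function(t) post_density(pp, t) * max(u_function(g_cdf(fam, t), prior), 0)
  ds_mode <- if (lo < hi) stats::optimize(f, c(lo, hi), maximum = TRUE)$maximum else theta[i_max]

  list(mle = unname(mle), peb_mean = unname(peb), ds_mean = unname(ds_mean),
       ds_median = unname(ds_median), ds_mode = unname(ds_mode))
}

# ---- macro-inference -------------------------------------------------------

#' Macro-inference summary with smooth-bootstrap standard errors
#'
#' Pools the k studies into overall summaries of the fitted prior: its mean,
#' its mode(s), and the naive pooled average.  Standard errors for the mode
#' locations come from the smooth parametric bootstrap: each replicate
#' samples latent parameters from the fitted prior, regenerates data with
#' the original exposures, reruns the full fitting pipeline (hyperparameter
#' start included), and recomputes the modes; replicate modes are matched to
#' the original ones by nearest location.
#'
#' @param fit A [ds_fit()] object.
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return A list of class \code{"ds_macro"}: \code{prior_mean},
#'   \code{pooled_naive}, \code{modes}, \code{mode_se}, \code{B_used},
#'   \code{seed}.
#' @export
macro_summary <- function(fit, B = 200, seed = 1) {
  stopifnot(inherits(fit, "ds_fit"))
  prior <- fit$prior
  gq <- gauss_nodes(128)
  d <- u_function(gq$x, prior)
  pm <- sum(gq$w * g_quantile(fit$family, gq$x) * pmax(d, 0)) /
    sum(gq$w * pmax(d, 0))
  pooled <- if (fit$family$family == "binomial") {
    sum(fit$data$y) / sum(fit$data$exposure)
  } else mean(fit$data$y)
  modes <- ds_modes(prior)$location

  mode_se <- rep(NA_real_, length(modes))
  n_used <- 0
  if (B > 0 && length(modes) > 0) {
    set.seed(seed)
    half_gap <- if (length(modes) > 1) min(diff(sort(modes))) / 2 else Inf
    boot <- matrix(NA_real_, B, length(modes))
    for (b in seq_len(B)) {
      rep_fit <- tryCatch({
        dat <- simulate_ds(prior, fit$data$k, fit$data$exposure)
        ds_fit(dat$y, dat$exposure, fit$family$family,
               start = if (fit$start == "user") "user" else fit$start,
               g_par = if (fit$start == "user") unname(fit$family$hyper) else NULL,
               m_max = length(fit$raw_coef))
      }, error = function(e) NULL)
      if (is.null(rep_fit)) next
      rep_modes <- ds_modes(rep_fit$prior)$location
      if (!length(rep_modes)) next
      n_used <- n_used + 1
      for (mi in seq_along(modes)) {
        dist <- abs(rep_modes - modes[mi])
        j <- which.min(dist)
        if (dist[j] <= half_gap) boot[b, mi] <- rep_modes[j]
      }
    }
    mode_se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  }
  structure(list(prior_mean = unname(pm), pooled_naive = unname(pooled),
                 modes = modes, mode_se = mode_se, B_used = n_used,
                 B = B, seed = seed),
            class = "ds_macro")
}

#' @export
print.ds_macro <- function(x, ...) {
  cat("Macro-inference summary\n")
  cat("  prior mean  :", signif(x$prior_mean, 4), "\n")
  cat("  naive pooled:", signif(x$pooled_naive, 4), "\n")
  if (length(x$modes)) {
    se <- ifelse(is.na(x$mode_se), "NA", signif(x$mode_se, 3))
    cat("  modes       :",
        paste(sprintf("%s (+/- %s)", signif(x$modes, 4), se), collapse = ", "), "\n")
    cat("  bootstrap   :", x$B_used, "of", x$B, "replicates used (seed", x$seed, ")\n")
  } else cat("  no interior modes\n")
  invisible(x)
}

#' Cluster studies on their posterior modes
#'
#' K-means partition of the per-study DS posterior modes, with multiple
#' seeded restarts; groups are labelled in order of ascending centroid so
#' group 1 is the lowest-valued cluster.
#'
#' @param modes Numeric vector of posterior modes (e.g. the \code{ds_mode}
#'   column of [predict.ds_fit()]), or that data frame itself.
#' @param n_groups Number of clusters.
#' @param seed Integer seed for the restarts.
#' @return Integer vector of group labels (1 = lowest centroid).
#' @export
group_studies <- function(modes, n_groups = 2, seed = 1) {
  if (is.data.frame(modes)) modes <- modes$ds_mode
  if (n_groups < 1) stop("'n_groups' must be at least 1")
  if (n_groups > length(modes)) stop("more groups than studies")
  if (length(unique(modes)) < n_groups) {
    # degenerate: fewer distinct values than clusters
    return(as.integer(factor(rank(modes, ties.method = "min"))))
  }
  set.seed(seed)
  km <- stats::kmeans(modes, centers = n_groups, nstart = 25)
  relabel <- rank(km$centers)
  as.integer(relabel[km$cluster])
}
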