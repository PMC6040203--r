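#' Fit a DS(G, m) empirical-Bayes model
#'
#' The main entry point of the package.  Given k parallel studies, the
#' function (i) sets the conjugate anchor \eqn{g(\theta;\alpha,\beta)} --
#' by marginal maximum likelihood, the Jeffreys prior, or user-supplied
#' hyperparameters -- and (ii) estimates the nonparametric correction
#' coefficients by the Type-II method of moments with BIC smoothing
#' ([mom2_fit()]).  The result carries the fitted [ds_prior()] together
#' with diagnostics (qLP, BIC path, convergence) and supports the usual
#' modelling verbs: \code{print}, \code{summary}, \code{coef},
#' \code{predict} (per-study and new-study posterior summaries),
#' \code{plot} (U-function and prior), \code{simulate}, \code{fitted} and
#' \code{logLik}.
#'
#' @param y Vector of observations: successes (binomial), counts (poisson),
#'   measurements (normal), or positive reals (exponential).
#' @param exposure Trials \code{n} (binomial) or standard errors \code{s}
#'   (normal); \code{NULL} otherwise.  A scalar is recycled.
#' @param family Family id: \code{"binomial"}, \code{"poisson"},
#'   \code{"normal"} or \code{"exponential"}.
#' @param start How to anchor the conjugate prior: \code{"mle"} (default),
#'   \code{"jeffreys"} (binomial Beta(1/2,1/2)), or \code{"user"} with
#'   \code{g_par}.
#' @param g_par Hyperparameters for \code{start = "user"}:
#'   \code{c(alpha, beta)} or \code{c(mu, tau2)}.
#' @param m_max Highest basis degree considered (default 8).
#' @param tol,max_iter,grid_size,method Passed to [mom2_fit()].
#' @return An object of class \code{"ds_fit"}.
#' @examples
#' d <- load_dataset("rat_tumor")
#' fit <- ds_fit(d$y, d$exposure, family = "binomial")
#' fit
#' coef(fit)
#' predict(fit, new_y = 4, new_exposure = 14)
#' @export
ds_fit <- function(y, exposure = NULL, family,
                   start = c("mle", "jeffreys", "user"), g_par = NULL,
                   m_max = 8, tol = 1e-9, max_iter = 5000, grid_size = 150,
                   method = c("sequential", "joint")) {
  start <- match.arg(start)
  fam <- switch(start,
    mle = fit_conjugate(y, exposure, family, "mle"),
    jeffreys = fit_conjugate(y, exposure, family, "jeffreys"),
    user = {
      if (is.null(g_par) || length(g_par) != 2) stop("start = 'user' needs g_par of length 2")
      if (family == "normal") conjugate_family("normal", mu = g_par[1], tau2 = g_par[2])
      else conjugate_family(family, g_par[1], g_par[2])
    })
  exposure <- validate_obs(fam, y, exposure)
  mom <- mom2_fit(y, exposure, fam, m_max = m_max, tol = tol,
                  max_iter = max_iter, grid_size = grid_size, method = method)
  structure(list(
    prior = mom$prior,
    family = fam,
    coef = mom$prior$coef,
    raw_coef = mom$raw_coef,
    bic_table = mom$bic_table,
    m = mom$m,
    qlp = mom$qlp,
    n_iter = mom$n_iter,
    converged = mom$converged,
    start = start,
    data = list(y = y, exposure = exposure, k = length(y)),
    call = match.call()
  ), class = "ds_fit")
}

#' @export
print.ds_fit <- function(x, ...) {
  cat("DS(G, m) empirical-Bayes fit\n")
  print(x$family)
  if (x$m == 0 || all(x$coef == 0)) {
    cat("Correction: none retained (the conjugate prior is adequate)\n")
  } else {
    nz <- which(x$coef != 0)
    cat("Correction: pi(theta) = g(theta) * [1",
        paste(sprintf("%+.3f T%d", x$coef[nz], nz), collapse = " "), "]\n")
  }
  cat("k =", x$data$k, " m =", x$m, " qLP =", signif(x$qlp, 4), "\n")
  invisible(x)
}

#' @export
summary.ds_fit <- function(object, ...) {
  structure(list(fit = object,
                 kl = kl_divergence(object$prior),
                 prior_mean_g = prior_mean(object$family),
                 modes = ds_modes(object$prior)),
            class = "summary.ds_fit")
}

#' @export
print.summary.ds_fit <- function(x, ...) {
  print(x$fit)
  cat("\nRaw coefficients:", paste(signif(x$fit$raw_coef, 3), collapse = " "), "\n")
  cat("BIC deviance path:", paste(signif(x$fit$bic_table$dev, 3), collapse = " "), "\n")
  cat("KL(pi || g) =", signif(x$kl, 4),
      " (qLP/2 =", signif(x$fit$qlp / 2, 4), ")\n")
  cat("Anchor prior mean =", signif(x$prior_mean_g, 4), "\n")
  if (nrow(x$modes)) {
    cat("Prior mode(s):", paste(signif(x$modes$location, 4), collapse = ", "), "\n")
  } else {
    cat("No interior prior mode (boundary-dominated shape)\n")
  }
  invisible(x)
}

#' @export
coef.ds_fit <- function(object, type = c("smoothed", "raw"), ...) {
  type <- match.arg(type)
  cf <- if (type == "raw") object$raw_coef else object$coef
  stats::setNames(cf, paste0("T", seq_along(cf)))
}

#' Posterior summaries for observed or new studies
#'
#' Micro-inference under the fitted DS prior.  For each requested study the
#' method returns the frequentist estimate, the parametric empirical-Bayes
#' (Stein) posterior mean, and the DS posterior mean/median/mode computed on
#' the model's support grid (see [ds_micro()]).
#'
#' @param object A [ds_fit()] object.
#' @param new_y,new_exposure New observation(s); defaults to the fitted data.
#' @param ... Unused.
#' @return A data frame with one row per study: \code{y}, \code{exposure},
#'   \code{mle}, \code{peb_mean}, \code{ds_mean}, \code{ds_median},
#'   \code{ds_mode}.
#' @export
predict.ds_fit <- function(object, new_y = NULL, new_exposure = NULL, ...) {
  if (is.null(new_y)) {
    new_y <- object$data$y
    new_exposure <- object$data$exposure
  } else {
    new_exposure <- validate_obs(object$family, new_y, new_exposure)
  }
  rows <- lapply(seq_along(new_y), function(i) {
    e_i <- if (is.null(new_exposure)) NULL else new_exposure[i]
    s <- ds_micro(object, new_y[i], e_i)
    data.frame(y = new_y[i],
               exposure = if (is.null(e_i)) NA_real_ else e_i,
               mle = s$mle, peb_mean = s$peb_mean, ds_mean = s$ds_mean,
               ds_median = s$ds_median, ds_mode = s$ds_mode)
  })
  do.call(rbind, rows)
}

#' @export
fitted.ds_fit <- function(object, ...) {
  predict(object)$ds_mean
}

#' Marginal log-likelihood under the fitted DS model
#'
#' Sum of \eqn{\log f_{LP}(y_i)} over the studies, using the closed-form LP marginal.
#' @param object A [ds_fit()] object.
#' @param ... Unused.
#' @export
logLik.ds_fit <- function(object, ...) {
  ll <- sum(log(vapply(seq_len(object$data$k), function(i) {
    e_i <- if (is.null(object$data$exposure)) NULL else object$data$exposure[i]
    marginal_lp(object$data$y[i], e_i, object$prior)
  }, numeric(1))))
  structure(ll, df = object$m + length(object$family$hyper),
            nobs = object$data$k, class = "logLik")
}

#' Simulate replicate data from a fitted DS model
#'
#' Draws latent parameters from the fitted prior and observations from the
#' likelihood, reusing the original exposures -- the smooth parametric
#' bootstrap underlying the macro-inference standard errors.
#'
#' @param object A [ds_fit()] object.
#' @param nsim Number of replicate data sets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of \code{nsim} lists with elements \code{theta}, \code{y},
#'   \code{exposure}.
#' @export
simulate.ds_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(r) {
    simulate_ds(object$prior, object$data$k, object$data$exposure)
  })
}

#' Plot a fitted DS model
#'
#' Two panels: the estimated U-function (departure from the flat line marks
#' prior-data conflict) and the DS prior against its conjugate anchor.
#'
#' @param x A [ds_fit()] object.
#' @param which Subset of panels, 1 (U-function) and/or 2 (priors).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ds_fit <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    uf <- u_function(NULL, x$prior)
    graphics::plot(uf$u, uf$d, type = "l", col = "firebrick", lwd = 2,
                   xlab = "u", ylab = "d(u)", main = "U-function", ...)
    graphics::abline(h = 1, lty = 3, col = "grey40")
  }
  if (2 %in% which) {
    fam <- x$family
    rng <- switch(fam$family,
      binomial = c(1e-4, 1 - 1e-4),
      normal = fam$hyper["mu"] + c(-1, 1) * 4 * sqrt(fam$hyper["tau2"]),
      c(1e-4, g_quantile(fam, 0.999)))
    th <- seq(rng[1], rng[2], length.out = 500)
    gd <- g_density(fam, th)
    dd <- suppressWarnings(ds_density(th, x$prior, warn = FALSE))
    graphics::matplot(th, cbind(gd, pmax(dd, 0)), type = "l",
                      lty = c(2, 1), col = c("steelblue", "firebrick"), lwd = 2,
                      xlab = "theta", ylab = "density", main = "Prior: conjugate vs DS")
    graphics::legend("topright", c("conjugate g", "DS prior"),
                     lty = c(2, 1), col = c("steelblue", "firebrick"), bty = "n")
  }
  invisible(x)
}
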