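#' Conjugate likelihood/prior families
#'
#' Constructs one of the four conjugate pairs underlying the DS(G,m) model:
#' \describe{
#'   \item{binomial}{\eqn{y_i \sim \mathrm{Bin}(n_i, \theta_i)}, prior
#'     \eqn{\mathrm{Beta}(\alpha, \beta)}; marginal beta-binomial; posterior
#'     \eqn{\mathrm{Beta}(\alpha+y, \beta-y+n)}.}
#'   \item{poisson}{\eqn{y_i \sim \mathrm{Pois}(\theta_i)}, prior
#'     \eqn{\mathrm{Gamma}(\alpha, \beta)} with \emph{scale} \eqn{\beta};
#'     marginal negative binomial with \eqn{p = 1/(1+\beta)}; posterior
#'     \eqn{\mathrm{Gamma}(\alpha+y, \beta/(1+\beta))}.}
#'   \item{normal}{\eqn{y_i \sim N(\theta_i, s_i^2)} with known \eqn{s_i},
#'     prior \eqn{N(\mu, \tau^2)}; marginal \eqn{N(\mu, s_i^2+\tau^2)};
#'     posterior \eqn{N(\lambda\mu + (1-\lambda)y, (1-\lambda)s^2)} with
#'     \eqn{\lambda = s^2/(s^2+\tau^2)}.}
#'   \item{exponential}{\eqn{y_i \sim \mathrm{Exp}(\theta_i)} (rate), prior
#'     \eqn{\mathrm{Gamma}(\alpha, \beta)} (scale); marginal Lomax
#'     \eqn{\alpha\beta/(1+\beta y)^{\alpha+1}}; posterior
#'     \eqn{\mathrm{Gamma}(\alpha+1, \beta/(1+\beta y))}.}
#' }
#'
#' @param family One of \code{"binomial"}, \code{"poisson"}, \code{"normal"},
#'   \code{"exponential"}.
#' @param alpha,beta Shape hyperparameters (beta/gamma priors); both > 0.
#' @param mu,tau2 Mean and variance of the normal prior; \code{tau2 > 0}
#'   (\code{tau2 = 0} is tolerated as a degenerate limit in internal use).
#' @return An object of class \code{"conj_family"}.
#' @examples
#' conjugate_family("binomial", alpha = 2.3, beta = 14.1)
#' conjugate_family("normal", mu = 13.2, tau2 = 1.85^2)
#' @export
conjugate_family <- function(family = c("binomial", "poisson", "normal", "exponential"),
                             alpha = NULL, beta = NULL, mu = NULL, tau2 = NULL) {
  family <- match.arg(family)
  if (family == "normal") {
    if (is.null(mu) || is.null(tau2)) stop("normal family needs 'mu' and 'tau2'")
    if (tau2 < 0) stop("'tau2' must be non-negative")
    hyper <- c(mu = as.numeric(mu), tau2 = as.numeric(tau2))
  } else {
    if (is.null(alpha) || is.null(beta)) stop(family, " family needs 'alpha' and 'beta'")
    if (alpha <= 0 || beta <= 0) stop("'alpha' and 'beta' must be positive")
    hyper <- c(alpha = as.numeric(alpha), beta = as.numeric(beta))
  }
  structure(list(family = family, hyper = hyper), class = "conj_family")
}

#' @export
print.conj_family <- function(x, ...) {
  h <- paste(names(x$hyper), signif(x$hyper, 5), sep = " = ", collapse = ", ")
  cat("Conjugate family:", x$family, "(", h, ")\n")
  invisible(x)
}

# ---- prior G: density, CDF, quantile, support ------------------------------

g_density <- function(fam, theta) {
  h <- fam$hyper
  switch(fam$family,
    binomial    = stats::dbeta(theta, h["alpha"], h["beta"]),
    poisson     = stats::dgamma(theta, h["alpha"], scale = h["beta"]),
    exponential = stats::dgamma(theta, h["alpha"], scale = h["beta"]),
    normal      = stats::dnorm(theta, h["mu"], sqrt(h["tau2"])))
}

g_cdf <- function(fam, theta) {
  h <- fam$hyper
  switch(fam$family,
    binomial    = stats::pbeta(theta, h["alpha"], h["beta"]),
    poisson     = stats::pgamma(theta, h["alpha"], scale = h["beta"]),
    exponential = stats::pgamma(theta, h["alpha"], scale = h["beta"]),
    normal      = stats::pnorm(theta, h["mu"], sqrt(h["tau2"])))
}

g_quantile <- function(fam, u) {
  h <- fam$hyper
  switch(fam$family,
    binomial    = stats::qbeta(u, h["alpha"], h["beta"]),
    poisson     = stats::qgamma(u, h["alpha"], scale = h["beta"]),
    exponential = stats::qgamma(u, h["alpha"], scale = h["beta"]),
    normal      = stats::qnorm(u, h["mu"], sqrt(h["tau2"])))
}

check_support <- function(fam, theta) {
  bad <- switch(fam$family,
    binomial    = any(theta < 0 | theta > 1),
    poisson     = any(theta < 0),
    exponential = any(theta < 0),
    normal      = FALSE)
  if (isTRUE(bad)) stop("theta outside the support of the prior")
  invisible(TRUE)
}

prior_mean <- function(fam) {
  h <- fam$hyper
  switch(fam$family,
    binomial    = unname(h["alpha"] / (h["alpha"] + h["beta"])),
    poisson     = unname(h["alpha"] * h["beta"]),
    exponential = unname(h["alpha"] * h["beta"]),
    normal      = unname(h["mu"]))
}

# ---- observation validation ------------------------------------------------

validate_obs <- function(fam, y, exposure) {
  switch(fam$family,
    binomial = {
      if (is.null(exposure)) stop("binomial data need the number of trials n")
      if (length(exposure) == 1L) exposure <- rep(exposure, length(y))
      if (length(exposure) != length(y)) stop("lengths of y and n differ")
      if (any(y < 0 | y > exposure) || any(y != round(y)) || any(exposure != round(exposure)))
        stop("binomial data need integer 0 <= y <= n")
    },
    poisson = {
      if (any(y < 0) || any(y != round(y))) stop("poisson counts must be non-negative integers")
      exposure <- NULL
    },
    normal = {
      if (is.null(exposure)) stop("normal data need per-study standard errors s")
      if (length(exposure) == 1L) exposure <- rep(exposure, length(y))
      if (length(exposure) != length(y)) stop("lengths of y and s differ")
      if (any(exposure <= 0)) stop("standard errors must be positive")
    },
    exponential = {
      if (any(y <= 0)) stop("exponential observations must be positive")
      exposure <- NULL
    })
  exposure
}

# ---- conjugate closed forms: marginals and posteriors ----------------------

#' Conjugate marginal density f_G(y)
#'
#' The marginal distribution of one observation under the pure conjugate
#' model: beta-binomial, negative binomial, normal with inflated variance, or
#' Lomax, according to the family.
#'
#' @param y Observation(s).
#' @param exposure Binomial trials \code{n} or normal standard error
#'   \code{s}; \code{NULL} for poisson/exponential.
#' @param family A [conjugate_family()].
#' @return Marginal density/pmf values.
#' @export
marginal_g <- function(y, exposure = NULL, family) {
  stopifnot(inherits(family, "conj_family"))
  exposure <- validate_obs(family, y, exposure)
  h <- family$hyper
  switch(family$family,
    binomial = {
      n <- exposure
      exp(lchoose(n, y) + lbeta(h["alpha"] + y, h["beta"] + n - y) - lbeta(h["alpha"], h["beta"]))
    },
    poisson = {
      p <- 1 / (1 + h["beta"])
      exp(lgamma(y + h["alpha"]) - lgamma(h["alpha"]) - lfactorial(y) +
            h["alpha"] * log(p) + y * log1p(-p))
    },
    normal = stats::dnorm(y, h["mu"], sqrt(exposure^2 + h["tau2"])),
    exponential = h["alpha"] * h["beta"] / (1 + h["beta"] * y)^(h["alpha"] + 1))
}

#' Conjugate posterior parameters
#'
#' Parameters of the closed-form posterior of \eqn{\theta_i} given one
#' observation, exactly as the conjugate algebra dictates.
#'
#' @inheritParams marginal_g
#' @return A list with \code{dist} (\code{"beta"}, \code{"gamma"} or
#'   \code{"normal"}) and its parameters (\code{shape1/shape2},
#'   \code{shape/scale}, or \code{mean/var}).
#' @export
posterior_g <- function(y, exposure = NULL, family) {
  stopifnot(inherits(family, "conj_family"), length(y) == 1L)
  exposure <- validate_obs(family, y, exposure)
  h <- family$hyper
  switch(family$family,
    binomial = list(dist = "beta",
                    shape1 = unname(h["alpha"] + y),
                    shape2 = unname(h["beta"] - y + exposure)),
    poisson = list(dist = "gamma",
                   shape = unname(h["alpha"] + y),
                   scale = unname(h["beta"] / (1 + h["beta"]))),
    normal = {
      lam <- exposure^2 / (exposure^2 + h["tau2"])
      list(dist = "normal",
           mean = unname(lam * h["mu"] + (1 - lam) * y),
           var = unname((1 - lam) * exposure^2))
    },
    exponential = list(dist = "gamma",
                       shape = unname(h["alpha"] + 1),
                       scale = unname(h["beta"] / (1 + h["beta"] * y))))
}

post_density <- function(pp, theta) {
  switch(pp$dist,
    beta   = stats::dbeta(theta, pp$shape1, pp$shape2),
    gamma  = stats::dgamma(theta, pp$shape, scale = pp$scale),
    normal = stats::dnorm(theta, pp$mean, sqrt(pp$var)))
}

post_quantile <- function(pp, v) {
  switch(pp$dist,
    beta   = stats::qbeta(v, pp$shape1, pp$shape2),
    gamma  = stats::qgamma(v, pp$shape, scale = pp$scale),
    normal = stats::qnorm(v, pp$mean, sqrt(pp$var)))
}

post_mean_closed <- function(pp) {
  switch(pp$dist,
    beta   = pp$shape1 / (pp$shape1 + pp$shape2),
    gamma  = pp$shape * pp$scale,
    normal = pp$mean)
}

# ---- hyperparameter estimation ---------------------------------------------

#' Fit conjugate-prior hyperparameters by marginal maximum likelihood
#'
#' Maximises the product of conjugate marginals \eqn{\prod_i f_G(y_i)} over
#' the hyperparameters.  For the normal family the mean is profiled out
#' (\eqn{\hat\mu(\tau^2) = \sum w_i y_i / \sum w_i}, \eqn{w_i = 1/(s_i^2+\tau^2)})
#' and a one-dimensional bounded search is used on
#' \eqn{\tau^2 \in [0, 10\,\mathrm{var}(y)]}; the boundary \eqn{\hat\tau^2 = 0}
#' is allowed.  The other families are maximised on the log scale by
#' Nelder-Mead.  \code{method = "jeffreys"} returns the Beta(1/2, 1/2) prior
#' instead (binomial only), useful when the number of studies is tiny.
#'
#' @param y Vector of observations (length \eqn{k \ge 2}).
#' @param exposure Trials \code{n} (binomial) or standard errors \code{s}
#'   (normal); \code{NULL} otherwise.
#' @param family Family id string.
#' @param method \code{"mle"} or \code{"jeffreys"}.
#' @return A [conjugate_family()] object with fitted hyperparameters.
#' @examples
#' d <- load_dataset("navy_shipyard")
#' fit_conjugate(d$y, d$exposure, "binomial", method = "jeffreys")
#' @export
fit_conjugate <- function(y, exposure = NULL, family, method = c("mle", "jeffreys")) {
  method <- match.arg(method)
  fam0 <- switch(family,
    binomial    = conjugate_family("binomial", 1, 1),
    poisson     = conjugate_family("poisson", 1, 1),
    exponential = conjugate_family("exponential", 1, 1),
    normal      = conjugate_family("normal", mu = 0, tau2 = 1),
    stop("unknown family: ", family))
  exposure <- validate_obs(fam0, y, exposure)
  if (method == "jeffreys") {
    if (family != "binomial") stop("the Jeffreys start is defined for the binomial family")
    return(conjugate_family("binomial", 0.5, 0.5))
  }
  k <- length(y)
  if (k < 2) stop("need at least two studies to estimate hyperparameters")

  if (family == "normal") {
    nll <- function(tau2) {
      w <- 1 / (exposure^2 + tau2)
      mu <- sum(w * y) / sum(w)
      -sum(stats::dnorm(y, mu, sqrt(exposure^2 + tau2), log = TRUE))
    }
    upper <- max(10 * stats::var(y), 1e-8)
    opt <- stats::optimize(nll, c(0, upper))
    tau2 <- opt$minimum
    if (nll(0) <= opt$objective) tau2 <- 0   # boundary solution
    w <- 1 / (exposure^2 + tau2)
    return(conjugate_family("normal", mu = sum(w * y) / sum(w), tau2 = tau2))
  }

  if (all(y == y[1])) {
    boundary <- switch(family,
      binomial = all(y == 0) || all(y == exposure),
      poisson = all(y == 0),
      exponential = FALSE)
    if (boundary)
      stop("hyperparameters are not identifiable: all observations sit on the support boundary")
  }

  nll <- function(p) {
    fam <- conjugate_family(family, exp(p[1]), exp(p[2]))
    v <- marginal_g(y, exposure, fam)
    if (any(!is.finite(v)) || any(v <= 0)) return(1e10)
    -sum(log(v))
  }
  opt <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("marginal-likelihood optimisation did not converge (code ",
         opt$convergence, ", value ", signif(opt$value, 6), ")")
  conjugate_family(family, exp(opt$par[1]), exp(opt$par[2]))
}

# ---- posterior expectations of basis functions -----------------------------

#' Posterior expectation of a rank polynomial, E_G[T_j | y]
#'
#' Computes \eqn{E_G[\mathrm{Leg}_j(G(\Theta)) \mid y]} under the conjugate
#' posterior by 64-node Gauss-Legendre quadrature after the change of
#' variables to the posterior CDF scale
#' (\eqn{\int_0^1 \mathrm{Leg}_j(G(Q_{post}(v)))\,dv}), where the integrand is
#' bounded and smooth.  A doubled-node rule is available through
#' \code{nodes} for accuracy checks.
#'
#' @param j Basis degree (0 returns exactly 1).
#' @inheritParams marginal_g
#' @param nodes Number of quadrature nodes.
#' @return A scalar in \eqn{[-\sqrt{2j+1}, \sqrt{2j+1}]}.
#' @export
posterior_expect_T <- function(j, y, exposure = NULL, family, nodes = 128) {
  if (j == 0) return(1)
  posterior_expect_hT(function(theta) 1, j, y, exposure, family, nodes)
}

#' Posterior expectation E_G[h(Theta) T_j | y]
#'
#' Generalisation of [posterior_expect_T()] with an extra factor
#' \eqn{h(\theta)} in the integrand; \code{h = identity} gives the mixed
#' moments needed by the Elastic-Bayes estimator.
#'
#' @param h Function of theta (vectorised); defaults to identity.
#' @inheritParams posterior_expect_T
#' @export
posterior_expect_hT <- function(h = identity, j, y, exposure = NULL, family, nodes = 128) {
  stopifnot(inherits(family, "conj_family"), length(y) == 1L)
  exposure <- validate_obs(family, y, exposure)
  pp <- posterior_g(y, exposure, family)
  gq <- gauss_nodes(nodes)
  theta <- post_quantile(pp, gq$x)
  u <- g_cdf(family, theta)
  vals <- h(theta) * leg_poly(j, u)
  if (any(!is.finite(vals))) stop("non-finite integrand in posterior expectation")
  sum(gq$w * vals)
}

# Vectorised internal version: all degrees 1..m at once, plus mixed moments
# with h(theta) = theta.  Used by the inference layer.
post_expectations <- function(y, exposure, family, m, nodes = 128) {
  pp <- posterior_g(y, exposure, family)
  gq <- gauss_nodes(nodes)
  theta <- post_quantile(pp, gq$x)
  L <- leg_matrix(g_cdf(family, theta), m)
  list(ET = as.vector(crossprod(L, gq$w)),
       EthT = as.vector(crossprod(L, gq$w * theta)),
       Eth = sum(gq$w * theta))
}

# ---- delimited-text readers ------------------------------------------------

#' Read study data from delimited text
#'
#' Reads the two-column layouts used throughout the package: (y, n) for
#' binomial, (y, s) for normal, and a single count column or a
#' (value, frequency) table for poisson (the frequency table is expanded to
#' an individual-level vector).  Comma or tab delimiters are auto-detected
#' and a header row is optional.
#'
#' @param path File path.
#' @param family Family id string.
#' @return A list with \code{y}, \code{exposure} (possibly \code{NULL}) and
#'   \code{k}.
#' @export
read_study_data <- function(path, family) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  probe <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE)
  header <- any(is.na(suppressWarnings(as.numeric(unlist(probe)))))
  df <- utils::read.table(path, sep = sep, header = header)
  as_study_data(df, family)
}

as_study_data <- function(df, family) {
  df <- as.data.frame(df)
  fam0 <- conjugate_family(if (family == "normal") "normal" else family,
                           alpha = 1, beta = 1, mu = 0, tau2 = 1)
  if (family %in% c("binomial", "normal")) {
    if (ncol(df) < 2) stop(family, " data need two columns")
    y <- as.numeric(df[[1]]); expo <- as.numeric(df[[2]])
    expo <- validate_obs(fam0, y, expo)
    return(list(y = y, exposure = expo, k = length(y)))
  }
  if (family == "poisson" && ncol(df) >= 2) {
    val <- as.numeric(df[[1]]); freq <- as.numeric(df[[2]])
    if (any(freq < 0) || any(freq != round(freq))) stop("frequencies must be non-negative integers")
    y <- rep(val, freq)
  } else {
    y <- as.numeric(df[[1]])
  }
  validate_obs(fam0, y, NULL)
  list(y = y, exposure = NULL, k = length(y))
}
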