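# Shared fixtures: built in code, no stored binaries.

# 128-node Gauss-Legendre quadrature of f on [0,1]
quad01 <- function(f) {
  gq <- pracma::gaussLegendre(128, 0, 1)
  sum(gq$w * f(gq$x))
}

# Random DS prior with a strictly positive correction: coefficients are
# scaled so that sum |c_j| * sqrt(2j+1) < 1, which bounds the series away
# from flipping sign.
random_positive_prior <- function(family, m = 4) {
  raw <- stats::runif(m, -1, 1)
  scale <- 0.9 / sum(abs(raw) * sqrt(2 * seq_len(m) + 1))
  ds_prior(family, raw * scale * stats::runif(1))
}

fam_binom <- function(a = 2, b = 5) conjugate_family("binomial", a, b)
fam_pois <- function(a = 1.5, b = 0.6) conjugate_family("poisson", a, b)
fam_norm <- function(mu = 1, tau2 = 2) conjugate_family("normal", mu = mu, tau2 = tau2)
fam_exp <- function(a = 2, b = 0.5) conjugate_family("exponential", a, b)

# all four families with arbitrary (but fixed) hyperparameters
all_families <- function() {
  list(fam_binom(2.3, 7.1), fam_pois(0.8, 1.4), fam_norm(-0.5, 1.7), fam_exp(1.9, 0.8))
}

post_density_for_test <- function(pp, theta) dspriors:::post_density(pp, theta)

# numeric integral of a function over the support of the family's prior
integrate_support <- function(fam, f) {
  rng <- switch(fam$family,
    binomial = c(0, 1),
    normal = fam$hyper["mu"] + c(-1, 1) * 20 * sqrt(fam$hyper["tau2"]),
    c(0, Inf))
  stats::integrate(f, rng[1], rng[2], rel.tol = 1e-9)$value
}
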