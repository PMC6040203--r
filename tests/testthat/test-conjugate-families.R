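test_that("conjugate marginals are proper distributions", {
  fb <- fam_binom(2.3, 7.1)
  expect_equal(sum(marginal_g(0:12, 12, fb)), 1, tolerance = 1e-12)
  fp <- fam_pois(0.8, 1.4)
  expect_equal(sum(marginal_g(0:400, NULL, fp)), 1, tolerance = 1e-10)
  fn <- fam_norm(-0.5, 1.7)
  expect_equal(integrate(function(y) marginal_g(y, 1.2, fn), -Inf, Inf)$value,
               1, tolerance = 1e-8)
  fe <- fam_exp(1.9, 0.8)
  expect_equal(integrate(function(y) marginal_g(y, NULL, fe), 0, Inf)$value,
               1, tolerance = 1e-6)
})

test_that("marginal closed forms match known special cases", {
  # uniform prior, one trial: both outcomes equally likely
  expect_equal(marginal_g(0:1, 1, fam_binom(1, 1)), c(0.5, 0.5))
  # unit-shape gamma prior: geometric marginal 2^-(y+1)
  expect_equal(marginal_g(0:6, NULL, fam_pois(1, 1)), 2^-(1:7), tolerance = 1e-12)
  # normal marginal peaks at the prior mean with inflated variance
  fn <- fam_norm(3, 2)
  expect_equal(marginal_g(3, 1.5, fn), 1 / sqrt(2 * pi * (1.5^2 + 2)))
})

test_that("conjugate posteriors carry the exact updated parameters", {
  pp <- posterior_g(7, 32, fam_binom(2.3, 14.08))
  expect_equal(pp$shape1, 2.3 + 7)
  expect_equal(pp$shape2, 14.08 + 25)
  pp <- posterior_g(0, NULL, fam_pois(0.7, 0.31))
  expect_equal(pp$shape, 0.7)
  expect_equal(pp$scale, 0.31 / 1.31)
  # equal sampling and prior variance: posterior mean is the midpoint
  pp <- posterior_g(4, sqrt(2), fam_norm(1, 2))
  expect_equal(pp$mean, (1 + 4) / 2)
  pp <- posterior_g(2, NULL, fam_exp(1.9, 0.8))
  expect_equal(pp$shape, 2.9)
  expect_equal(pp$scale, 0.8 / (1 + 0.8 * 2))
})

test_that("Bayes rule factorises the joint density in all four families", {
  cases <- list(
    list(fam = fam_binom(2.3, 7.1), y = 3, ex = 10,
         lik = function(t, y) dbinom(y, 10, t), grid = seq(0.01, 0.99, 0.02)),
    list(fam = fam_pois(0.8, 1.4), y = 2, ex = NULL,
         lik = function(t, y) dpois(y, t), grid = seq(0.05, 8, 0.1)),
    list(fam = fam_norm(-0.5, 1.7), y = 0.8, ex = 1.1,
         lik = function(t, y) dnorm(y, t, 1.1), grid = seq(-4, 4, 0.1)),
    list(fam = fam_exp(1.9, 0.8), y = 1.4, ex = NULL,
         lik = function(t, y) dexp(y, t), grid = seq(0.05, 8, 0.1)))
  for (cs in cases) {
    lhs <- cs$lik(cs$grid, cs$y) * g_density(cs$fam, cs$grid)
    pp <- posterior_g(cs$y, cs$ex, cs$fam)
    rhs <- marginal_g(cs$y, cs$ex, cs$fam) * post_density_for_test(pp, cs$grid)
    expect_equal(lhs, rhs, tolerance = 1e-10, label = cs$fam$family)
  }
})

test_that("marginal maximum likelihood recovers generating hyperparameters", {
  set.seed(31)
  k <- 5000
  theta <- rbeta(k, 2, 5)
  y <- rbinom(k, 20, theta)
  fit <- fit_conjugate(y, 20, "binomial")
  expect_equal(unname(fit$hyper["alpha"]), 2, tolerance = 0.12)
  expect_equal(unname(fit$hyper["beta"]), 5, tolerance = 0.12)

  theta <- rgamma(k, 1.5, scale = 0.6)
  y <- rpois(k, theta)
  fit <- fit_conjugate(y, NULL, "poisson")
  expect_equal(unname(fit$hyper["alpha"]), 1.5, tolerance = 0.12)
  expect_equal(unname(fit$hyper["beta"]), 0.6, tolerance = 0.12)

  s <- runif(k, 0.5, 1.5)
  theta <- rnorm(k, 2, sqrt(0.8))
  y <- rnorm(k, theta, s)
  fit <- fit_conjugate(y, s, "normal")
  expect_equal(unname(fit$hyper["mu"]), 2, tolerance = 0.05)
  expect_equal(unname(fit$hyper["tau2"]), 0.8, tolerance = 0.12)
})

test_that("binomial data symmetric under y -> n - y give alpha = beta", {
  y <- c(2, 5, 8, 3, 7, 1, 9, 4, 6, 5)
  y <- c(y, 10 - y)
  fit <- fit_conjugate(y, 10, "binomial")
  expect_equal(unname(fit$hyper["alpha"]), unname(fit$hyper["beta"]),
               tolerance = 1e-4)
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(fit_conjugate(rep(0, 10), 5, "binomial"), "boundary")
  expect_error(fit_conjugate(rep(0, 10), NULL, "poisson"), "boundary")
  expect_error(fit_conjugate(3, 5, "binomial"), "two studies")
  expect_error(marginal_g(6, 5, fam_binom()), "y <= n")
  expect_error(marginal_g(-1, NULL, fam_pois()), "non-negative")
  expect_error(conjugate_family("binomial", -1, 2), "positive")
})

test_that("jeffreys start returns Beta(1/2, 1/2)", {
  fit <- fit_conjugate(c(0, 0, 0, 1, 5), 5, "binomial", method = "jeffreys")
  expect_equal(unname(fit$hyper), c(0.5, 0.5))
})

test_that("delimited readers handle layouts, headers and separators", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(y = c(1, 2), n = c(5, 6)), tmp, row.names = FALSE)
  d <- read_study_data(tmp, "binomial")
  expect_equal(d$y, c(1, 2))
  expect_equal(d$exposure, c(5, 6))

  tmp2 <- tempfile(fileext = ".tsv")
  writeLines(c("0\t3", "1\t2"), tmp2)   # headerless frequency table
  d2 <- read_study_data(tmp2, "poisson")
  expect_equal(sort(d2$y), c(0, 0, 0, 1, 1))
  expect_equal(d2$k, 5)

  tmp3 <- tempfile(fileext = ".csv")
  writeLines(c("y,s", "1.2,0.4", "0.8,0.6"), tmp3)
  d3 <- read_study_data(tmp3, "normal")
  expect_equal(d3$exposure, c(0.4, 0.6))

  expect_error(read_study_data(tempfile(), "binomial"), "no such file")
})
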