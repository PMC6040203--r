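test_that("the ratio-form posterior expectation is normalised", {
  set.seed(3)
  fam <- fam_binom(2, 6)
  for (r in 1:10) {
    pr <- ds_prior(fam, runif(3, -0.4, 0.4))
    y <- sample(0:8, 1)
    expect_equal(posterior_mean_lp(function(t) rep(1, length(t)), y, 8, pr), 1,
                 tolerance = 1e-12)
  }
})

test_that("zero correction reduces every LP quantity to its conjugate form", {
  fam <- fam_pois(1.3, 0.5)
  pr0 <- ds_prior(fam)
  expect_equal(marginal_lp(2, NULL, pr0), marginal_g(2, NULL, fam))
  th <- seq(0.05, 4, 0.05)
  expect_equal(posterior_lp(th, 2, NULL, pr0),
               post_density_for_test(posterior_g(2, NULL, fam), th))
  expect_equal(elastic_bayes(2, NULL, pr0), stein_peb(2, NULL, fam))
  # quadrature route to the same closed-form quantity
  expect_equal(posterior_mean_lp(identity, 2, NULL, pr0),
               stein_peb(2, NULL, fam), tolerance = 1e-4)
})

test_that("LP marginal matches brute-force integration of the defining mixture", {
  set.seed(17)
  fam <- fam_binom(2.5, 5.5)
  for (r in 1:20) {
    pr <- ds_prior(fam, runif(sample(2:4, 1), -0.35, 0.35))
    n <- sample(5:15, 1)
    y <- sample(0:n, 1)
    direct <- integrate(function(t)
      dbinom(y, n, t) * ds_density(t, pr, warn = FALSE), 0, 1,
      rel.tol = 1e-10)$value
    expect_lt(abs(suppressWarnings(marginal_lp(y, n, pr)) - direct), 1e-6)
  }
  # the LP marginal is a proper distribution over the outcome space
  pr <- ds_prior(conjugate_family("binomial", 2.3, 14.08), c(0, 0, -0.5))
  expect_lt(abs(sum(suppressWarnings(vapply(0:9, function(y)
    marginal_lp(y, 9, pr), numeric(1)))) - 1), 1e-5)
})

test_that("LP posterior is a proper density and stabilises for large n", {
  pr <- ds_prior(conjugate_family("binomial", 0.5, 0.5), c(-0.72, 0.91))
  v <- integrate(function(t) posterior_lp(t, 0, 5, pr), 0, 1,
                 rel.tol = 1e-8)$value
  expect_lt(abs(v - 1), 1e-5)
  # overwhelming data: correction washes out of the posterior mean
  n <- 1e4; y <- 3000
  fam <- fam_binom(2, 6)
  pr2 <- ds_prior(fam, c(0.2, -0.2))
  expect_equal(elastic_bayes(y, n, pr2), stein_peb(y, n, fam), tolerance = 1e-3)
})

test_that("elastic Bayes equals the integrated LP posterior mean", {
  set.seed(23)
  fam <- fam_binom(1.8, 6.4)
  for (r in 1:8) {
    pr <- ds_prior(fam, runif(3, -0.35, 0.35))
    y <- sample(0:10, 1)
    direct <- integrate(function(t) t * posterior_lp(t, y, 10, pr), 0, 1,
                        rel.tol = 1e-10)$value
    expect_lt(abs(elastic_bayes(y, 10, pr) - direct), 1e-5)
  }
})

test_that("Stein shrinkage has the right form and limits", {
  fam <- conjugate_family("binomial", 2.30, 14.08)
  expect_equal(stein_peb(4, 14, fam), (4 + 2.30) / (14 + 16.38), tolerance = 1e-12)
  # weight moves fully onto the data as n grows
  expect_equal(stein_peb(9e5, 1e6, fam), 0.9, tolerance = 1e-4)
  # normal case: precision-weighted average
  fn <- fam_norm(1, 2)
  lam <- 1.5^2 / (1.5^2 + 2)
  expect_equal(stein_peb(4, 1.5, fn), lam * 1 + (1 - lam) * 4)
})

test_that("Robbins' rule reproduces frequency ratios with edge conventions", {
  counts <- c(10, 5, 0, 2)
  expect_equal(robbins(0, counts), 1 * 5 / 10)
  expect_equal(robbins(1, counts), 0)          # empty successor cell
  expect_true(is.na(robbins(2, counts)))       # empty current cell
  expect_true(is.na(robbins(3, counts)))       # successor outside the table
  expect_error(robbins(0, c(-1, 2)), "non-negative")
})

test_that("k-means grouping recovers separated clusters and orders labels", {
  set.seed(9)
  modes <- c(rnorm(12, 0.05, 0.004), rnorm(18, 0.3, 0.004))
  g <- group_studies(modes, 2, seed = 2)
  expect_equal(g, rep(c(1L, 2L), c(12, 18)))
  # degenerate case: identical modes collapse to one label
  expect_equal(unique(group_studies(rep(0.2, 6), 1)), 1L)
  expect_error(group_studies(modes, 40), "more groups")
})

test_that("estimator risk ordering matches the prior shape", {
  # true gamma prior: the parametric rule is best; clearly bimodal mixture:
  # the corrected rule beats it through selective shrinkage
  set.seed(77)
  k <- 1500
  ds_means <- function(fit, y) {
    uy <- sort(unique(y))
    tab <- vapply(uy, function(v) ds_micro(fit, v)$ds_mean, numeric(1))
    tab[match(y, uy)]
  }
  theta_g <- rgamma(k, 2, scale = 0.5)
  y_g <- rpois(k, theta_g)
  fit_g <- ds_fit(y_g, family = "poisson")
  pe_g <- stein_peb(y_g, NULL, fit_g$family)
  ds_g <- ds_means(fit_g, y_g)
  counts <- tabulate(y_g + 1, nbins = max(y_g) + 2)
  rb_g <- robbins(y_g, counts, values = 0:(max(y_g) + 1))
  rb_g[is.na(rb_g)] <- y_g[is.na(rb_g)]
  mse <- c(peb = mean((pe_g - theta_g)^2),
           ds = mean((ds_g - theta_g)^2),
           robbins = mean((rb_g - theta_g)^2))
  expect_lt(mse[["peb"]], mse[["ds"]] + 0.01)
  expect_lt(mse[["peb"]], mse[["robbins"]])

  theta_b <- ifelse(runif(k) < 0.5, rgamma(k, 10, scale = 0.05),
                    rgamma(k, 100, scale = 0.05))
  y_b <- rpois(k, theta_b)
  fit_b <- ds_fit(y_b, family = "poisson")
  pe_b <- stein_peb(y_b, NULL, fit_b$family)
  ds_b <- ds_means(fit_b, y_b)
  expect_lte(mean((ds_b - theta_b)^2), mean((pe_b - theta_b)^2))
})
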