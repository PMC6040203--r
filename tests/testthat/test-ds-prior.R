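test_that("DS density reduces to the anchor and integrates to one", {
  for (fam in all_families()) {
    pr0 <- ds_prior(fam)
    th <- switch(fam$family,
      binomial = seq(0.01, 0.99, 0.01),
      normal = seq(-4, 4, 0.1),
      seq(0.05, 6, 0.05))
    expect_equal(ds_density(th, pr0), g_density(fam, th), label = fam$family)
  }
  # normalisation holds for arbitrary coefficient vectors (signed included)
  set.seed(21)
  fam <- fam_binom(2.5, 6)
  for (r in 1:100) {
    cf <- runif(sample(1:5, 1), -0.6, 0.6)
    pr <- ds_prior(fam, cf)
    v <- integrate(function(t) suppressWarnings(ds_density(t, pr, warn = FALSE)),
                   0, 1, rel.tol = 1e-9)$value
    expect_equal(v, 1, tolerance = 1e-6)
  }
})

test_that("the U-function is the prior density ratio on the rank scale", {
  fam <- fam_pois(1.2, 0.7)
  pr <- ds_prior(fam, c(0.2, -0.15, 0.1))
  th <- seq(0.05, 5, 0.05)
  expect_equal(u_function(g_cdf(fam, th), pr),
               ds_density(th, pr, warn = FALSE) / g_density(fam, th),
               tolerance = 1e-12)
  # zero correction: flat at one
  expect_equal(u_function(seq(0, 1, 0.1), ds_prior(fam)), rep(1, 11))
  # integrates to one for any coefficients (orthogonality to constants)
  expect_equal(quad01(function(u) u_function(u, pr)), 1, tolerance = 1e-10)
})

test_that("qLP obeys Parseval's identity and approximates twice the KL", {
  fam <- fam_binom(3, 4)
  expect_equal(qlp(ds_prior(fam, c(0.3, -0.4))), 0.25)
  expect_equal(qlp(ds_prior(fam)), 0)
  set.seed(8)
  for (r in 1:20) {
    pr <- random_positive_prior(fam)
    # Parseval: int d^2 = 1 + qLP
    expect_equal(quad01(function(u) u_function(u, pr)^2), 1 + qlp(pr),
                 tolerance = 1e-8)
    expect_gte(kl_divergence(pr), 0)
    if (qlp(pr) > 1e-4 && qlp(pr) <= 0.1) {
      expect_equal(qlp(pr), 2 * kl_divergence(pr), tolerance = 0.1)
    }
  }
})

test_that("sampler draws from the corrected prior", {
  fam <- fam_binom(2, 5)
  # null correction: draws follow G itself
  x <- ds_sample(ds_prior(fam), 1e4, seed = 5)
  ks <- suppressWarnings(ks.test(x, function(q) pbeta(q, 2, 5)))
  expect_gt(ks$p.value, 0.01)
  # moment identity: sample means of T_j estimate the coefficients
  pr <- ds_prior(fam, c(0.25, -0.2))
  k <- 1e5
  x <- ds_sample(pr, k, seed = 9)
  u <- pbeta(x, 2, 5)
  for (j in 1:2) {
    expect_equal(mean(leg_poly(j, u)), pr$coef[j],
                 tolerance = 4 / sqrt(k) * sqrt(2 * j + 1))
  }
  # determinism
  expect_identical(ds_sample(pr, 50, seed = 3), ds_sample(pr, 50, seed = 3))
  expect_error(ds_sample(pr, 0), "positive")
})

test_that("mode finding locates interior maxima and flags boundary shapes", {
  # closed-form beta mode
  md <- ds_modes(ds_prior(fam_binom(2, 5)))
  expect_equal(md$location, 0.2, tolerance = 1e-4)
  expect_false(attr(md, "boundary"))
  # U-shaped Jeffreys prior: no interior mode
  md <- ds_modes(ds_prior(fam_binom(0.5, 0.5)))
  expect_equal(nrow(md), 0)
  expect_true(attr(md, "boundary"))
  # a two-term correction can split one mode into two
  pr <- ds_prior(conjugate_family("binomial", 2.3, 14.08), c(0, 0, -0.5))
  md <- ds_modes(pr)
  expect_equal(nrow(md), 2)
  expect_true(all(diff(md$location) > 0))
})

test_that("u-function grid export round-trips", {
  pr <- ds_prior(fam_binom(2, 5), c(0.1, -0.1))
  f <- tempfile(fileext = ".csv")
  write_u_function(pr, f, grid_size = 101)
  uf <- read.csv(f)
  expect_equal(nrow(uf), 101)
  expect_equal(uf$d, u_function(uf$u, pr), tolerance = 1e-12)
})
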