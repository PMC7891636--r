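test_that("inverse Gaussian density is correct and normalised", {
  expect_equal(dinvgauss(1, 1, 1), 1 / sqrt(2 * pi))
  total <- integrate(function(x) dinvgauss(x, 0.5, 2), 0, Inf,
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  m <- integrate(function(x) x * dinvgauss(x, 0.25, 1), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(m, 0.25, tolerance = 1e-8)
  expect_error(dinvgauss(-1, 1, 1))
  expect_error(dinvgauss(1, -1, 1))
})

test_that("IG is the index -1/2 special case of the GIG", {
  g1 <- ig_to_gig(1, 1)
  expect_equal(unclass(g1)[c("index", "coef_x", "coef_invx")],
               list(index = -0.5, coef_x = 1, coef_invx = 1))
  g2 <- ig_to_gig(2, 8)
  expect_equal(g2$coef_x, 2)
  expect_equal(g2$coef_invx, 8)
  # quadrature mean of the mapped GIG equals the IG mean
  for (prm in list(c(1, 1), c(0.3, 2.5), c(4, 0.7))) {
    gg <- ig_to_gig(prm[1], prm[2])
    expect_equal(quad_gig_moment(gg$index, gg$coef_x, gg$coef_invx, 1),
                 prm[1], tolerance = 1e-8)
  }
  # density shapes agree after renormalisation
  x <- c(0.2, 0.7, 1.9)
  expect_equal(dgig(x, ig_to_gig(0.8, 1.7)), dinvgauss(x, 0.8, 1.7),
               tolerance = 1e-12)
})

test_that("Bessel ratios match closed forms and stay stable at extremes", {
  # half-integer closed forms: K_{1/2}/K_{3/2} = x/(x+1)
  expect_equal(besselK_ratio(1 / 2, 2), 2 / 3, tolerance = 1e-14)
  x <- c(0.1, 1, 10)
  expect_equal(besselK_ratio(1 / 2, x), x / (x + 1), tolerance = 1e-13)
  # K_{3/2}/K_{5/2} = x(1 + x)/(3 + 3x + x^2)
  expect_equal(besselK_ratio(3 / 2, x), x * (1 + x) / (3 + 3 * x + x^2),
               tolerance = 1e-12)
  # reference value at integer order
  expect_equal(besselK_ratio(0, 1), besselK(1, 0) / besselK(1, 1),
               tolerance = 1e-14)
  expect_equal(besselK_ratio(0, 1), 0.42102 / 0.60191, tolerance = 1e-4)
  # monotone increasing in the argument, limit 1
  r <- besselK_ratio(2, c(1, 10, 100, 1e4, 1e6))
  expect_true(all(diff(r) > 0))
  expect_equal(r[5], 1, tolerance = 1e-5)
  # no overflow/underflow at large order and argument
  extremes <- expand.grid(order = c(0, 0.5, 10, 1e3, 1e4),
                          arg = c(1e-3, 1, 1e3, 1e6))
  for (i in seq_len(nrow(extremes))) {
    v <- besselK_ratio(extremes$order[i], extremes$arg[i])
    expect_true(is.finite(v) && v > 0 && v <= 1)
  }
  # negative orders through K_{-nu} = K_nu
  expect_equal(besselK_ratio(-1 / 2, 3), 1)
  expect_equal(besselK_ratio(-3 / 2, 3), 1 / besselK_ratio(1 / 2, 3),
               tolerance = 1e-12)
  expect_error(besselK_ratio(1, -2))
})

test_that("GIG moments agree with adaptive quadrature to 1e-8", {
  grid <- expand.grid(index = c(-5, -1, -1 / 2, 0, 2),
                      nu = c(0.01, 1, 100), eta = c(0.01, 1, 100))
  for (i in seq_len(nrow(grid))) {
    prm <- gig(grid$index[i], grid$nu[i], grid$eta[i])
    for (k in c(-2L, -1L, 1L, 2L)) {
      expect_equal(gig_moment(prm, k),
                   quad_gig_moment(prm$index, prm$coef_x, prm$coef_invx, k),
                   tolerance = 1e-8,
                   label = sprintf("moment %d at (%g, %g, %g)", k,
                                   prm$index, prm$coef_x, prm$coef_invx))
    }
    # Cauchy-Schwarz: E[X] E[1/X] >= 1
    expect_gte(gig_moment(prm, 1) * gig_moment(prm, -1), 1)
  }
})

test_that("GIG moments reproduce the inverse Gaussian identities", {
  for (prm in list(c(0.5, 1), c(1, 1), c(2, 8), c(0.1, 3))) {
    gg <- ig_to_gig(prm[1], prm[2])
    expect_equal(gig_moment(gg, 1), prm[1], tolerance = 1e-12)
    expect_equal(gig_moment(gg, -1), 1 / prm[1] + 1 / prm[2],
                 tolerance = 1e-12)
  }
  # reference value: E[1/X] for GIG(-1, 1, 1) = K_0(1)/K_1(1) + 2
  expect_equal(gig_moment(gig(-1, 1, 1), -1), 2.69947, tolerance = 1e-5)
})

test_that("NIG prior variance and kurtosis match the scale-mixture oracle", {
  pm <- nig_prior_moments(1, 1, 1, 1)
  expect_equal(pm$variance, 1)
  expect_equal(pm$kurtosis, 12)
  expect_error(nig_prior_moments(-1, 1, 1, 1))
  # Monte Carlo oracle: kurtosis = 3 E[v^2]/E[v]^2 with v = gamma2 * tau2
  set.seed(99)
  n <- 2e6
  for (cfg in list(c(1, 1, 1, 1), c(0.5, 0.25, 1, 2))) {
    v <- rinvgauss(n, cfg[1], cfg[3]) * rinvgauss(n, cfg[2], cfg[4])
    k_mc <- 3 * mean(v^2) / mean(v)^2
    k_an <- nig_prior_moments(cfg[1], cfg[2], cfg[3], cfg[4])$kurtosis
    expect_equal(k_an, k_mc, tolerance = 0.02)
  }
})

test_that("shrinkage-weight density integrates to one and follows the change of variables", {
  total <- quad_unit(function(k) dkappa_nig(k, 1, 1))
  expect_equal(total, 1, tolerance = 1e-6)
  expect_equal(dkappa_nig(0.5, 1, 1), dinvgauss(1, 1, 1) * 4,
               tolerance = 1e-12)
  expect_error(dkappa_nig(0, 1, 1))
  expect_error(dkappa_nig(1, 1, 1))
  # growing prior mean shifts mass towards kappa = 0 (less shrinkage):
  # the mass above 1/2 shrinks monotonically and the median drops below 1/2
  upper_mass <- vapply(c(1, 100, 1e4), function(phi)
    integrate(function(k) dkappa_nig(k, phi, 1), 0.5, 1,
              rel.tol = 1e-8)$value, numeric(1))
  expect_true(all(diff(upper_mass) < 0))
  expect_lt(upper_mass[3], 0.5)
})

test_that("random variate generators match their analytic moments", {
  set.seed(4)
  x <- rinvgauss(2e5, 0.5, 2)
  expect_equal(mean(x), 0.5, tolerance = 0.01)
  expect_equal(var(x), 0.5^3 / 2, tolerance = 0.05)
  prm <- gig(-1, 1.5, 2)
  g <- rgig(2e4, prm)
  expect_equal(mean(g), gig_moment(prm, 1), tolerance = 0.03)
  expect_equal(mean(1 / g), gig_moment(prm, -1), tolerance = 0.03)
  # a positive-index case exercises the other tail of the sampler
  prm2 <- gig(2.5, 0.8, 3)
  g2 <- rgig(2e4, prm2)
  expect_equal(mean(g2), gig_moment(prm2, 1), tolerance = 0.03)
})
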