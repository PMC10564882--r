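test_that("linear predictor evaluates the slope decomposition term by term", {
  p <- model_parameters(beta1 = 1, beta2 = 1.0, beta3 = 0, sigma_r = 1,
                        r = c(0.5, -0.2), cutpoints = -2:2)
  # cond = 0: all slope terms vanish, only the CIA baseline remains
  expect_equal(linear_predictor(p, cia = 0.4, cond = 0, i = 1), 0.4)
  # cond = 1 with zero covariate effects: beta1 + r_i
  p2 <- model_parameters(1, 0, 0, 1, r = c(0.5, -0.2), cutpoints = -2:2)
  expect_equal(linear_predictor(p2, cia = 0.9, cond = 1, i = 1), 1.5)
  # full arithmetic: 0.3 + 0.182 + 0.231
  p3 <- model_parameters(0.5, 0.26, 0.33, 1, r = c(0, -0.2),
                         cutpoints = -2:2)
  expect_equal(linear_predictor(p3, cia = 0.7, cond = 1, i = 2),
               0.3 + 0.182 + 0.231)
  expect_error(linear_predictor(p3, 0.7, 1, i = 3), "index")
})

test_that("category probabilities form a simplex and match the normal-CDF oracle", {
  tau <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  set.seed(7)
  for (eta in c(-20, rnorm(8, 0, 2), 20)) {
    pr <- category_probs(eta, tau)
    expect_length(pr, 7L)
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
  # symmetric case: middle category mass from the standard-normal CDF
  pr0 <- category_probs(0, tau)
  expect_equal(pr0[4], pnorm(0.5) - pnorm(-0.5), tolerance = 1e-12)
  expect_equal(pr0, rev(pr0))
  # saturation at extreme latent means
  expect_gt(category_probs(20, tau)[7], 1 - 1e-10)
  expect_error(category_probs(0, c(0, 0, 1)), "increasing")
})

test_that("probabilities are invariant to joint location shifts and reflect correctly", {
  tau <- c(-1.2, -0.3, 0.4, 2.0)
  set.seed(11)
  for (i in 1:5) {
    eta <- rnorm(1)
    shift <- rnorm(1, 0, 3)
    expect_equal(category_probs(eta + shift, tau + shift),
                 category_probs(eta, tau), tolerance = 1e-12)
    # negate the latent mean and negate-reverse the cutpoints: the
    # probability vector reverses
    expect_equal(category_probs(-eta, rev(-tau)),
                 rev(category_probs(eta, tau)), tolerance = 1e-12)
  }
})

test_that("log-likelihood is additive and matches a quadrature oracle", {
  set.seed(23)
  # single observation equals the log of its category probability
  d1 <- make_data(cia = c(0.5, 0.7), y_async = c(3, 4), y_sync = c(5, 2))
  p <- random_params(2, 7)
  ll_manual <- 0
  for (i in 1:2) {
    for (cond in 0:1) {
      y <- d1$ratings[i, cond + 1L]
      eta <- linear_predictor(p, d1$cia[[i]], cond, i)
      ll_manual <- ll_manual + log(category_probs(eta, p$cutpoints)[y])
    }
  }
  expect_equal(log_likelihood(p, d1), ll_manual, tolerance = 1e-12)

  # quadrature oracle: P(Y = k) by numerical integration of the
  # standard-normal density of the latent residual over (tau_{k-1} - eta,
  # tau_k - eta], on 10 random parameter/data draws
  for (rep_i in 1:10) {
    n <- sample(2:5, 1L)
    K <- sample(c(5L, 7L), 1L)
    d <- make_data(cia = runif(n), y_async = sample.int(K, n, TRUE),
                   y_sync = sample.int(K, n, TRUE), K = K)
    p <- random_params(n, K)
    ll_quad <- 0
    for (i in seq_len(n)) {
      for (cond in 0:1) {
        y <- d$ratings[i, cond + 1L]
        eta <- linear_predictor(p, d$cia[[i]], cond, i)
        lo <- c(-Inf, p$cutpoints)[y] - eta
        hi <- c(p$cutpoints, Inf)[y] - eta
        pk <- stats::integrate(stats::dnorm, lo, hi, rel.tol = 1e-12,
                               abs.tol = 0)$value
        ll_quad <- ll_quad + log(max(pk, 1e-300))
      }
    }
    expect_equal(log_likelihood(p, d), ll_quad, tolerance = 1e-8)
  }

  expect_error(log_likelihood(random_params(3, 7), d1), "participants")
})

test_that("log-likelihood drops when an observation moves to a less probable category", {
  d <- make_data(cia = c(0.5, 0.6), y_async = c(4, 4), y_sync = c(4, 4))
  p <- model_parameters(0, 0, 0, 1, r = c(0, 0),
                        cutpoints = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5))
  base <- log_likelihood(p, d)
  d_swap <- make_data(cia = c(0.5, 0.6), y_async = c(7, 4), y_sync = c(4, 4))
  expect_lt(log_likelihood(p, d_swap), base)
})

test_that("log-prior assembles the closed-form component densities", {
  prior <- prior_config()
  tau <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  p0 <- model_parameters(0, 0, 0, sigma_r = 1.3, r = c(0, 0, 0),
                         cutpoints = tau)
  lp <- log_prior(p0, prior)
  coef_part <- 3 * dnorm(0, 0, 2.5, log = TRUE)
  # half-Cauchy(0, 2.5) log density: log(2 / (pi * g * (1 + (x/g)^2)))
  sigma_part <- log(2 / (pi * 2.5 * (1 + (1.3 / 2.5)^2)))
  r_part <- 3 * dnorm(0, 0, 1.3, log = TRUE)
  tau_part <- sum(dt(tau / 2.5, df = 3, log = TRUE) - log(2.5))
  expect_equal(lp, coef_part + sigma_part + r_part + tau_part,
               tolerance = 1e-12)
  # at sigma = scale the half-Cauchy density is 1 / (pi * scale)
  p1 <- model_parameters(0, 0, 0, sigma_r = 2.5, r = numeric(0),
                         cutpoints = tau)
  expect_equal(log_prior(p1, prior) -
                 (coef_part + tau_part),
               log(2 / (pi * 2.5)) - log(2), tolerance = 1e-12)

  # adding participants with r_i = 0 adds N Normal(0, sigma_r) terms
  pN <- model_parameters(0, 0, 0, 1.3, r = rep(0, 6), cutpoints = tau)
  expect_equal(log_prior(pN, prior) - lp, 3 * dnorm(0, 0, 1.3, log = TRUE),
               tolerance = 1e-12)

  # alternative sigma families agree with stats:: densities
  for (fam in c("half_normal", "exponential", "half_t")) {
    pr <- prior_config(sigma_family = fam, sigma_scale = 1.7)
    got <- log_prior(p1, pr) - (coef_part + tau_part)
    want <- switch(fam,
      half_normal = log(2) + dnorm(2.5, 0, 1.7, log = TRUE),
      exponential = dexp(2.5, 1 / 1.7, log = TRUE),
      half_t = log(2) + dt(2.5 / 1.7, 3, log = TRUE) - log(1.7))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("log-posterior adds likelihood and prior and respects exchangeability", {
  set.seed(31)
  d <- make_data(cia = c(0.2, 0.8, 0.5), y_async = c(1, 4, 3),
                 y_sync = c(6, 7, 2))
  p <- random_params(3, 7)
  prior <- prior_config()
  expect_equal(log_posterior(p, d, prior),
               log_likelihood(p, d) + log_prior(p, prior))
  expect_equal(log_posterior(p, d, prior, include_likelihood = FALSE),
               log_prior(p, prior))

  # permuting participants together with their r_i leaves it unchanged
  perm <- c(3L, 1L, 2L)
  d_perm <- make_data(cia = as.numeric(d$cia)[perm],
                      y_async = d$ratings[perm, "async"],
                      y_sync = d$ratings[perm, "sync"])
  p_perm <- model_parameters(p$beta1, p$beta2, p$beta3, p$sigma_r,
                             r = p$r[perm], cutpoints = p$cutpoints)
  expect_equal(log_posterior(p_perm, d_perm, prior),
               log_posterior(p, d, prior), tolerance = 1e-12)
})

test_that("prior configuration round-trips through YAML and JSON files", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("sigma_family: half_normal", "sigma_scale: 1.0",
               "coef_scale: 5"), path)
  pr <- read_prior_config(path)
  expect_equal(pr$sigma$family, "half_normal")
  expect_equal(pr$sigma$scale, 1.0)
  expect_equal(pr$coef$scale, 5)
  jpath <- tempfile(fileext = ".json")
  writeLines('{"coef_family": "student_t", "coef_df": 7}', jpath)
  prj <- read_prior_config(jpath)
  expect_equal(prj$coef$family, "student_t")
  expect_equal(prj$coef$df, 7)
  bad <- tempfile(fileext = ".yaml")
  writeLines("sigma_scales: 3", bad)
  expect_error(read_prior_config(bad), "unknown prior configuration key")
})
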