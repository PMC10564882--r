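# Shared small fit reused across blocks (N = 24, short chains): enough to
# exercise dimensions, determinism and summaries without long runtimes.
small_data <- simulate_dataset(generator_config(24, beta1 = 1, beta2 = 0,
                                                beta3 = 0.3, sigma_r = 1,
                                                seed = 404))
small_cfg <- mcmc_config(n_chains = 2L, n_iterations = 400L,
                         n_warmup = 200L, seed = 99L)
small_fit <- sample_posterior(small_data, config = small_cfg)

test_that("draws have the configured dimensions, labels and constraints", {
  K <- small_data$n_categories
  n <- length(small_data$participants)
  expect_equal(nrow(small_fit), 2L * 200L)
  expect_equal(parameter_names(small_fit),
               c("beta1", "beta2", "beta3", "sigma_r",
                 paste0("tau_", seq_len(K - 1L)),
                 paste0("r_", small_data$participants)))
  expect_true(all(small_fit$sigma_r > 0))
  tau <- as.matrix(small_fit[, paste0("tau_", seq_len(K - 1L))])
  expect_true(all(apply(tau, 1L, function(x) all(diff(x) > 0))))
  expect_equal(sort(unique(small_fit$.chain)), 1:2)
})

test_that("identical seed, config and data reproduce draws bitwise", {
  again <- sample_posterior(small_data, config = small_cfg)
  expect_identical(as.data.frame(again), as.data.frame(small_fit))
  other <- sample_posterior(small_data,
                            config = mcmc_config(2L, 400L, 200L, seed = 100L))
  expect_false(identical(other$beta1, small_fit$beta1))
})

test_that("mcmc_config rejects degenerate run settings", {
  expect_error(mcmc_config(n_chains = 1L), "n_chains")
  expect_error(mcmc_config(n_iterations = 100L, n_warmup = 100L),
               "n_warmup")
})

test_that("R-hat is near 1 for well-mixed chains and large for shifted chains", {
  # same-distribution chains
  set.seed(500)
  m <- 1000L
  same <- make_draws(beta1 = rnorm(4 * m), beta2 = rnorm(4 * m),
                     beta3 = rnorm(4 * m), sigma_r = rexp(4 * m) + 0.1,
                     r_mat = matrix(rnorm(4 * m), ncol = 1,
                                    dimnames = list(NULL, "a")),
                     cutpoints_mat = matrix(0, 4 * m, 2) +
                       cbind(rnorm(4 * m), rnorm(4 * m) + 5),
                     n_chains = 4L)
  expect_lt(rhat(same, "beta1"), 1.05)
  expect_lt(rhat(same, "beta1", method = "classic"), 1.05)

  # two chains centred 10 SDs apart: between-chain variance dominates.
  # classic-formula oracle on the split chains for the exact value.
  x1 <- rnorm(m, 0, 1); x2 <- rnorm(m, 10, 1)
  shifted <- make_draws(beta1 = c(x1, x2), beta2 = rnorm(2 * m),
                        beta3 = rnorm(2 * m), sigma_r = rexp(2 * m) + 0.1,
                        r_mat = matrix(rnorm(2 * m), ncol = 1,
                                       dimnames = list(NULL, "a")),
                        cutpoints_mat = cbind(rnorm(2 * m),
                                              rnorm(2 * m) + 5),
                        n_chains = 2L)
  expect_gt(rhat(shifted, "beta1"), 1.5)
  halves <- list(x1[1:500], x1[501:1000], x2[1:500], x2[501:1000])
  W <- mean(sapply(halves, var))
  B <- 500 * var(sapply(halves, mean))
  oracle <- sqrt((499 / 500 * W + B / 500) / W)
  expect_equal(rhat(shifted, "beta1", method = "classic"), oracle,
               tolerance = 1e-12)

  # degenerate constant chains return 1 by convention
  const <- make_draws(beta1 = rep(1, 40), beta2 = rep(0, 40),
                      beta3 = rep(0, 40), sigma_r = rep(1, 40),
                      r_mat = matrix(0, 40, 1,
                                     dimnames = list(NULL, "a")),
                      cutpoints_mat = cbind(rep(-1, 40), rep(1, 40)))
  expect_equal(rhat(const, "beta1"), 1)
  expect_error(rhat(small_fit, "nonexistent"), "unknown parameter")
})

test_that("posterior summaries use order statistics and intervals as declared", {
  toy <- make_draws(beta1 = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
                    beta2 = rep(0.5, 10), beta3 = rep(0, 10),
                    sigma_r = rep(1, 10),
                    r_mat = matrix(0, 10, 1, dimnames = list(NULL, "a")),
                    cutpoints_mat = cbind(rep(-1, 10), rep(1, 10)))
  s <- summarize_posterior(toy, "beta1")
  expect_equal(s$median, 3)
  expect_equal(s$lower, unname(quantile(toy$beta1, 0.025)))
  expect_equal(s$upper, unname(quantile(toy$beta1, 0.975)))
  # constant draws give a zero-width interval at the constant
  s2 <- summarize_posterior(toy, "beta2")
  expect_equal(c(s2$median, s2$lower, s2$upper), rep(0.5, 3L))
  expect_error(summarize_posterior(toy, "zzz"), "unknown parameter")
})

test_that("HPDI is the shortest window and narrower than equal-tailed on skewed draws", {
  # uniform grid: 96 of 101 points span width 0.95; exact-integer grid
  # pins the leftmost tie-break, the unit grid checks the width
  expect_equal(hpdi(0:100, 0.95), c(0, 95))
  grid <- seq(0, 1, by = 0.01)
  h01 <- hpdi(grid, 0.95)
  expect_equal(h01[2] - h01[1], 0.95, tolerance = 1e-9)
  # all equal: zero width
  expect_equal(hpdi(rep(2.2, 50), 0.95), c(2.2, 2.2))
  # mass near 1: the full range
  expect_equal(hpdi(grid, 0.9999), c(0, 1))
  expect_error(hpdi(numeric(0)), "at least 2")
  expect_error(hpdi(grid, 1.2), "between 0 and 1")

  # exhaustive window-search oracle on right-skewed samples, and
  # comparison with the equal-tailed interval width
  set.seed(77)
  for (i in 1:5) {
    x <- rexp(501)
    h <- hpdi(x, 0.9)
    s <- sort(x)
    m <- ceiling(0.9 * length(s))
    widths <- sapply(seq_len(length(s) - m + 1L),
                     function(j) s[j + m - 1L] - s[j])
    j <- which.min(widths)
    expect_equal(h, c(s[j], s[j + m - 1L]))
    eti <- unname(quantile(x, c(0.05, 0.95)))
    expect_lte(h[2] - h[1], eti[2] - eti[1])
  }
})

test_that("convergence report flags shifted parameters and passes vacuously when empty", {
  cv <- convergence_report(small_fit, parameters = c("beta1", "sigma_r"))
  expect_s3_class(cv, "rhi_convergence")
  expect_equal(cv$parameter, c("beta1", "sigma_r"))

  set.seed(9)
  m <- 500L
  bad <- make_draws(beta1 = c(rnorm(m), rnorm(m, 8)), beta2 = rnorm(2 * m),
                    beta3 = rnorm(2 * m), sigma_r = rexp(2 * m) + 0.1,
                    r_mat = matrix(rnorm(2 * m), ncol = 1,
                                   dimnames = list(NULL, "a")),
                    cutpoints_mat = cbind(rnorm(2 * m), rnorm(2 * m) + 5),
                    n_chains = 2L)
  cv_bad <- convergence_report(bad, parameters = c("beta1", "beta2"))
  expect_false(attr(cv_bad, "overall_pass"))
  expect_equal(cv_bad$parameter[!cv_bad$pass], "beta1")

  cv_empty <- convergence_report(small_fit, parameters = character(0))
  expect_equal(nrow(cv_empty), 0L)
  expect_true(attr(cv_empty, "overall_pass"))

  td <- trace_data(small_fit, "beta1")
  expect_equal(nrow(td), nrow(small_fit))
  expect_named(td, c("parameter", "chain", "iteration", "value"))
})

test_that("centered and non-centered parameterizations agree on the same posterior", {
  d <- simulate_dataset(generator_config(40, beta1 = 1.2, beta2 = -0.3,
                                         beta3 = 0.5, sigma_r = 1,
                                         seed = 71))
  cfg <- mcmc_config(n_chains = 2L, n_iterations = 2000L, n_warmup = 1000L,
                     seed = 7L)
  nc <- sample_posterior(d, config = cfg, parameterization = "noncentered")
  ce <- sample_posterior(d, config = cfg, parameterization = "centered")
  for (p in c("beta1", "beta3", "sigma_r")) {
    mcse <- function(x) sd(x) / sqrt(length(x) / 20)  # conservative ESS
    tol <- 2 * (mcse(nc[[p]]) + mcse(ce[[p]]))
    expect_lt(abs(median(nc[[p]]) - median(ce[[p]])), tol)
  }
})

test_that("with the likelihood disabled the sampler recovers the prior of beta3", {
  d <- simulate_dataset(generator_config(10, seed = 5))
  pr <- sample_posterior(d, config = mcmc_config(n_chains = 2L,
                                                 n_iterations = 3000L,
                                                 n_warmup = 1000L,
                                                 seed = 21L),
                         include_likelihood = FALSE)
  # prior of beta3 is normal(0, 2.5): compare central quantiles within
  # Monte-Carlo error of 4000 correlated draws
  q <- quantile(pr$beta3, c(0.25, 0.5, 0.75))
  expect_lt(abs(q[[2]] - 0), 0.35)
  expect_lt(abs(q[[1]] - qnorm(0.25, 0, 2.5)), 0.5)
  expect_lt(abs(q[[3]] - qnorm(0.75, 0, 2.5)), 0.5)
  expect_true(all(pr$sigma_r > 0))
})

test_that("draws round-trip through the draws file and keep parameter naming", {
  path <- tempfile(fileext = ".csv")
  write_draws(small_fit, path)
  back <- read_draws(path)
  expect_equal(parameter_names(back), parameter_names(small_fit))
  expect_equal(as.data.frame(back), as.data.frame(small_fit),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(back, "participants"), attr(small_fit, "participants"))
})
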