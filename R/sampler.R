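#' MCMC run configuration
#'
#' Defaults follow the analysis protocol: 4 parallel chains of 4000
#' iterations each with the first 2000 discarded as warmup, yielding 8000
#' posterior draws. At least two chains are required because the R-hat
#' convergence diagnostic compares between-chain and within-chain
#' variability.
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_iterations Iterations per chain, warmup included.
#' @param n_warmup Warmup (adaptation) iterations discarded from the
#'   output; must be smaller than `n_iterations`.
#' @param seed Master integer seed. Chain c uses stream seed
#'   `seed + c - 1` (documented splitting rule), so runs with identical
#'   seed, configuration and data reproduce draws bitwise.
#' @param backend Sampler backend; `"metropolis"` is the built-in
#'   adaptive random-walk Metropolis-within-Gibbs sampler.
#' @return An object of class `rhi_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iterations = 4000L,
                        n_warmup = 2000L, seed = 1L,
                        backend = "metropolis") {
  n_chains <- as.integer(n_chains)
  n_iterations <- as.integer(n_iterations)
  n_warmup <- as.integer(n_warmup)
  if (n_chains < 2L) stop("n_chains must be >= 2 (R-hat needs multiple chains)")
  if (n_warmup >= n_iterations) stop("n_warmup must be < n_iterations")
  if (n_warmup < 0L) stop("n_warmup must be non-negative")
  backend <- match.arg(backend, c("metropolis"))
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 n_warmup = n_warmup, seed = as.integer(seed),
                 backend = backend),
            class = "rhi_mcmc_config")
}

#' Sample the posterior of the hierarchical ordered-probit model
#'
#' Runs the built-in adaptive random-walk Metropolis-within-Gibbs sampler.
#' Each scalar block (regression coefficients, log random-slope SD, each
#' cutpoint) gets a Gaussian random-walk proposal whose scale is adapted
#' during warmup toward a 0.44 acceptance rate; the N random-slope
#' coordinates are updated in a single vectorized sweep with per-coordinate
#' scales. Cutpoint proposals violating the ordering constraint are
#' rejected outright, which enforces `tau_1 < ... < tau_{K-1}` in every
#' draw.
#'
#' By default the random slopes use the non-centered parameterization
#' `r_i = sigma_r * z_i`, `z_i ~ Normal(0, 1)`, which decouples the slopes
#' from their SD and mixes better when `sigma_r` is small; the centered
#' parameterization (sampling `r_i` directly) targets the identical
#' posterior and is available for cross-checks. Two extra moves improve
#' mixing along known posterior ridges: the condition effect is internally
#' sampled as `beta1 + beta3 * mean(CIA)`, and a translation move shifts
#' `beta1` against the average random slope without changing the
#' likelihood.
#'
#' @param data An `rhi_data` object (see [assemble_dataset()]).
#' @param prior An `rhi_prior` object (default [prior_config()]).
#' @param config An `rhi_mcmc_config` object (default [mcmc_config()]).
#' @param parameterization `"noncentered"` (default) or `"centered"`
#'   random-slope parameterization.
#' @param include_likelihood If `FALSE`, the likelihood is dropped and the
#'   sampler targets the prior (prior-recovery checks).
#' @return An object of class `rhi_draws`: a data frame with one row per
#'   post-warmup (chain, iteration), columns `.chain`, `.iteration`,
#'   `beta1`, `beta2`, `beta3`, `sigma_r`, `tau_1..tau_{K-1}` and
#'   `r_<participant_id>`.
#' @export
sample_posterior <- function(data, prior = prior_config(),
                             config = mcmc_config(),
                             parameterization = c("noncentered", "centered"),
                             include_likelihood = TRUE) {
  stopifnot(inherits(data, "rhi_data"), inherits(prior, "rhi_prior"),
            inherits(config, "rhi_mcmc_config"))
  parameterization <- match.arg(parameterization)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    mat <- run_chain(data, prior, config, chain_seed = config$seed + ch - 1L,
                     noncentered = parameterization == "noncentered",
                     include_likelihood = include_likelihood)
    chains[[ch]] <- data.frame(.chain = ch,
                               .iteration = seq_len(nrow(mat)),
                               mat, check.names = FALSE)
  }
  out <- do.call(rbind, chains)
  rownames(out) <- NULL
  structure(out,
            class = c("rhi_draws", "data.frame"),
            participants = data$participants,
            n_categories = data$n_categories,
            mcmc_config = config,
            parameterization = parameterization)
}

# One chain of the adaptive Metropolis-within-Gibbs sampler. Returns a
# matrix of post-warmup draws on the reporting scale.
run_chain <- function(data, prior, config, chain_seed, noncentered,
                      include_likelihood) {
  set.seed(chain_seed)
  n <- length(data$participants)
  K <- data$n_categories
  cia <- as.numeric(data$cia)
  cbar <- mean(cia)
  y0 <- data$ratings[, "async"]
  y1 <- data$ratings[, "sync"]

  dcoef <- function(x) ls_log_density(x, prior$coef$family,
                                      prior$coef$location, prior$coef$scale,
                                      prior$coef$df)
  dtau <- function(x) ls_log_density(x, prior$cutpoint$family,
                                     prior$cutpoint$location,
                                     prior$cutpoint$scale, prior$cutpoint$df)
  dsig <- function(s) sigma_log_density(s, prior$sigma$family,
                                        prior$sigma$scale, prior$sigma$df)
  ll_of <- function(y, eta, tau) {
    if (include_likelihood) obs_log_prob(y, eta, tau) else numeric(length(y))
  }

  # --- initialization: empirical-frequency cutpoints, neutral effects,
  # --- per-chain jitter
  cnt <- tabulate(c(y0, y1), K)
  cum <- pmin(pmax(cumsum(cnt)[-K] / (2 * n), 1 / (4 * n)), 1 - 1 / (4 * n))
  tau <- stats::qnorm(cum)
  tau <- enforce_spacing(tau + stats::rnorm(K - 1L, 0, 0.05))
  b <- stats::rnorm(3L, 0, 0.1)        # (beta1c, beta2, beta3) internal
  ls <- stats::rnorm(1L, 0, 0.1)       # log sigma_r
  u <- stats::rnorm(n, 0, 0.1)         # z (noncentered) or r (centered)

  sigma <- exp(ls)
  rr <- if (noncentered) sigma * u else u
  # internal coefficient block: b[1] = beta1 + beta3 * cbar
  eta0 <- b[2] * cia
  eta1 <- (b[1] - b[3] * cbar) + rr + (b[2] + b[3]) * cia
  ll0 <- ll_of(y0, eta0, tau)
  ll1 <- ll_of(y1, eta1, tau)

  u_prior <- function(u, sigma) {
    if (noncentered) stats::dnorm(u, log = TRUE)
    else stats::dnorm(u, 0, sigma, log = TRUE)
  }
  beta_prior <- function(b) sum(dcoef(c(b[1] - b[3] * cbar, b[2], b[3])))
  if (!is.finite(beta_prior(b) + dsig(sigma) + sum(u_prior(u, sigma)) +
                 sum(dtau(tau)) + sum(ll0) + sum(ll1))) {
    stop("non-finite log-posterior at initialization")
  }

  # observation indices whose category probability involves tau_k
  idx0 <- lapply(seq_len(K - 1L), function(k) which(y0 == k | y0 == k + 1L))
  idx1 <- lapply(seq_len(K - 1L), function(k) which(y1 == k | y1 == k + 1L))

  # --- adaptive proposal scales (log scale), target acceptance 0.44
  # scalar moves: b1c, b2, b3, ls, slope-shift, location, b2/b3 exchange,
  # tau_1..tau_{K-1}
  n_scalar <- 7L + (K - 1L)
  lsc <- c(rep(log(0.2), 7L), rep(log(0.2), K - 1L))
  lsc_u <- rep(log(1), n)
  acc <- numeric(n_scalar); att <- numeric(n_scalar)
  acc_u <- numeric(n); att_u <- numeric(n)
  batch <- 0L

  n_keep <- config$n_iterations - config$n_warmup
  pnames <- c("beta1", "beta2", "beta3", "sigma_r",
              paste0("tau_", seq_len(K - 1L)),
              paste0("r_", data$participants))
  out <- matrix(NA_real_, n_keep, length(pnames),
                dimnames = list(NULL, pnames))

  for (it in seq_len(config$n_iterations)) {
    # -- beta1c (shifts every synchronous latent mean by a constant)
    p <- b[1] + exp(lsc[1]) * stats::rnorm(1L)
    eta1p <- eta1 + (p - b[1])
    ll1p <- ll_of(y1, eta1p, tau)
    bp <- b; bp[1] <- p
    d <- sum(ll1p) - sum(ll1) + beta_prior(bp) - beta_prior(b)
    att[1] <- att[1] + 1
    if (log(stats::runif(1L)) < d) {
      b <- bp; eta1 <- eta1p; ll1 <- ll1p; acc[1] <- acc[1] + 1
    }

    # -- beta2 (CIA main effect; enters both conditions)
    p <- b[2] + exp(lsc[2]) * stats::rnorm(1L)
    delta <- (p - b[2]) * cia
    eta0p <- eta0 + delta; eta1p <- eta1 + delta
    ll0p <- ll_of(y0, eta0p, tau); ll1p <- ll_of(y1, eta1p, tau)
    bp <- b; bp[2] <- p
    d <- sum(ll0p) - sum(ll0) + sum(ll1p) - sum(ll1) +
      beta_prior(bp) - beta_prior(b)
    att[2] <- att[2] + 1
    if (log(stats::runif(1L)) < d) {
      b <- bp; eta0 <- eta0p; eta1 <- eta1p; ll0 <- ll0p; ll1 <- ll1p
      acc[2] <- acc[2] + 1
    }

    # -- beta3 (interaction; enters sync through centered CIA)
    p <- b[3] + exp(lsc[3]) * stats::rnorm(1L)
    eta1p <- eta1 + (p - b[3]) * (cia - cbar)
    ll1p <- ll_of(y1, eta1p, tau)
    bp <- b; bp[3] <- p
    d <- sum(ll1p) - sum(ll1) + beta_prior(bp) - beta_prior(b)
    att[3] <- att[3] + 1
    if (log(stats::runif(1L)) < d) {
      b <- bp; eta1 <- eta1p; ll1 <- ll1p; acc[3] <- acc[3] + 1
    }

    # -- log sigma_r (with log-scale Jacobian)
    p <- ls + exp(lsc[4]) * stats::rnorm(1L)
    sigmap <- exp(p)
    att[4] <- att[4] + 1
    if (noncentered) {
      eta1p <- eta1 + (sigmap - sigma) * u
      ll1p <- ll_of(y1, eta1p, tau)
      d <- sum(ll1p) - sum(ll1) + dsig(sigmap) - dsig(sigma) + p - ls
      if (log(stats::runif(1L)) < d) {
        ls <- p; sigma <- sigmap; eta1 <- eta1p; ll1 <- ll1p
        acc[4] <- acc[4] + 1
      }
    } else {
      d <- dsig(sigmap) - dsig(sigma) + p - ls +
        sum(u_prior(u, sigmap)) - sum(u_prior(u, sigma))
      if (log(stats::runif(1L)) < d) {
        ls <- p; sigma <- sigmap; acc[4] <- acc[4] + 1
      }
    }

    # -- translation move along the beta1 / mean-slope ridge:
    #    shifts beta1c and the slopes oppositely, leaving eta1 unchanged
    cshift <- exp(lsc[5]) * stats::rnorm(1L)
    scale_u <- if (noncentered) sigma else 1
    up <- u - cshift / scale_u
    bp <- b; bp[1] <- b[1] + cshift
    d <- beta_prior(bp) - beta_prior(b) +
      sum(u_prior(up, sigma)) - sum(u_prior(u, sigma))
    att[5] <- att[5] + 1
    if (log(stats::runif(1L)) < d) {
      b <- bp; u <- up; acc[5] <- acc[5] + 1
    }

    # -- random slopes, one vectorized sweep with independent accepts
    up <- u + exp(lsc_u) * stats::rnorm(n)
    eta1p <- eta1 + scale_u * (up - u)
    ll1p <- ll_of(y1, eta1p, tau)
    d <- ll1p - ll1 + u_prior(up, sigma) - u_prior(u, sigma)
    keep <- log(stats::runif(n)) < d
    u[keep] <- up[keep]; eta1[keep] <- eta1p[keep]; ll1[keep] <- ll1p[keep]
    att_u <- att_u + 1; acc_u <- acc_u + keep

    # -- location move along the cutpoint/coefficient ridge: translate all
    #    cutpoints and compensate through beta1c and beta2 (the model has
    #    no intercept, so overall location is only softly identified)
    cloc <- exp(lsc[6]) * stats::rnorm(1L)
    taup <- tau + cloc
    bp <- b; bp[1] <- b[1] + cloc; bp[2] <- b[2] + cloc / cbar
    delta0 <- (bp[2] - b[2]) * cia
    eta0p <- eta0 + delta0
    eta1p <- eta1 + cloc + delta0
    ll0p <- ll_of(y0, eta0p, taup)
    ll1p <- ll_of(y1, eta1p, taup)
    d <- sum(ll0p) - sum(ll0) + sum(ll1p) - sum(ll1) +
      beta_prior(bp) - beta_prior(b) + sum(dtau(taup)) - sum(dtau(tau))
    att[6] <- att[6] + 1
    if (log(stats::runif(1L)) < d) {
      b <- bp; tau <- taup; eta0 <- eta0p; eta1 <- eta1p
      ll0 <- ll0p; ll1 <- ll1p; acc[6] <- acc[6] + 1
    }

    # -- exchange move between the CIA main effect and the interaction:
    #    raises beta2 while lowering beta3 (and beta1c) so that the
    #    synchronous means stay fixed; only the asynchronous likelihood
    #    moves, which is the direction the data constrain weakly
    dx <- exp(lsc[7]) * stats::rnorm(1L)
    bp <- b
    bp[2] <- b[2] + dx; bp[3] <- b[3] - dx; bp[1] <- b[1] - dx * cbar
    eta0p <- eta0 + dx * cia
    ll0p <- ll_of(y0, eta0p, tau)
    d <- sum(ll0p) - sum(ll0) + beta_prior(bp) - beta_prior(b)
    att[7] <- att[7] + 1
    if (log(stats::runif(1L)) < d) {
      b <- bp; eta0 <- eta0p; ll0 <- ll0p; acc[7] <- acc[7] + 1
    }

    # -- cutpoints, one at a time; only observations in categories k or
    #    k+1 involve tau_k
    for (k in seq_len(K - 1L)) {
      j <- 7L + k
      att[j] <- att[j] + 1
      p <- tau[k] + exp(lsc[j]) * stats::rnorm(1L)
      lo <- if (k > 1L) tau[k - 1L] else -Inf
      hi <- if (k < K - 1L) tau[k + 1L] else Inf
      if (p <= lo || p >= hi) next
      taup <- tau; taup[k] <- p
      i0 <- idx0[[k]]; i1 <- idx1[[k]]
      ll0p <- ll_of(y0[i0], eta0[i0], taup)
      ll1p <- ll_of(y1[i1], eta1[i1], taup)
      d <- sum(ll0p) - sum(ll0[i0]) + sum(ll1p) - sum(ll1[i1]) +
        dtau(p) - dtau(tau[k])
      if (log(stats::runif(1L)) < d) {
        tau <- taup; ll0[i0] <- ll0p; ll1[i1] <- ll1p; acc[j] <- acc[j] + 1
      }
    }

    # -- warmup adaptation in batches of 50 iterations
    if (it <= config$n_warmup && it %% 50L == 0L) {
      batch <- batch + 1L
      step <- min(0.5, 1 / sqrt(batch))
      lsc <- lsc + ifelse(acc / pmax(att, 1) > 0.44, step, -step)
      lsc_u <- lsc_u + ifelse(acc_u / pmax(att_u, 1) > 0.44, step, -step)
      acc[] <- 0; att[] <- 0; acc_u[] <- 0; att_u[] <- 0
    }

    if (it > config$n_warmup) {
      rr <- if (noncentered) sigma * u else u
      out[it - config$n_warmup, ] <-
        c(b[1] - b[3] * cbar, b[2], b[3], sigma, tau, rr)
    }
  }
  out
}

# Force strict increase with a minimum spacing (initialization guard for
# empty categories, which produce tied empirical cutpoints).
enforce_spacing <- function(tau, eps = 1e-3) {
  for (k in seq_along(tau)[-1L]) {
    if (tau[k] <= tau[k - 1L] + eps) tau[k] <- tau[k - 1L] + eps
  }
  tau
}

#' @export
print.rhi_draws <- function(x, ...) {
  cfg <- attr(x, "mcmc_config")
  cat("<rhi_draws> ", nrow(x), " draws (", cfg$n_chains, " chains x ",
      cfg$n_iterations - cfg$n_warmup, " post-warmup iterations), ",
      ncol(x) - 2L, " parameters\n", sep = "")
  core <- intersect(c("beta1", "beta2", "beta3", "sigma_r"), names(x))
  med <- vapply(core, function(p) stats::median(x[[p]]), numeric(1))
  cat("  posterior medians: ",
      paste(sprintf("%s = %.3f", core, med), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Names of the sampled parameters
#'
#' @param draws An `rhi_draws` object.
#' @return Character vector of parameter column names (label columns
#'   `.chain` and `.iteration` excluded).
#' @export
parameter_names <- function(draws) {
  setdiff(names(draws), c(".chain", ".iteration"))
}

#' Write / read posterior draws
#'
#' The draws file is a CSV with one row per (chain, iteration) and one
#' column per parameter, named exactly as in the `rhi_draws` object
#' (`beta1, beta2, beta3, sigma_r, tau_k, r_<participant_id>`), so a
#' report regenerated from a saved file equals the in-memory one.
#'
#' @param draws An `rhi_draws` object.
#' @param path File path.
#' @return `write_draws`: `path`, invisibly. `read_draws`: an
#'   `rhi_draws` object (with metadata reconstructed from the file).
#' @export
write_draws <- function(draws, path) {
  utils::write.csv(as.data.frame(draws), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c(".chain", ".iteration") %in% names(df))) {
    stop("draws file must contain '.chain' and '.iteration' columns")
  }
  pids <- sub("^r_", "", grep("^r_", names(df), value = TRUE))
  n_tau <- sum(grepl("^tau_", names(df)))
  chains <- sort(unique(df$.chain))
  iters <- max(df$.iteration)
  structure(df,
            class = c("rhi_draws", "data.frame"),
            participants = pids,
            n_categories = n_tau + 1L,
            mcmc_config = structure(
              list(n_chains = length(chains), n_iterations = iters,
                   n_warmup = 0L, seed = NA_integer_,
                   backend = "metropolis"),
              class = "rhi_mcmc_config"),
            parameterization = NA_character_)
}
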