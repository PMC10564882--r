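#' Parameter set of the hierarchical ordered-probit model
#'
#' The model places a standard-normal latent intensity behind each
#' manifest ordinal rating. For participant i under condition
#' `cond` (0 = asynchronous, 1 = synchronous) the latent mean is
#'
#'   eta = (beta1 + r_i) * cond + beta2 * CIA_i + beta3 * cond * CIA_i
#'
#' so each participant's illusion susceptibility — the individual effect
#' of synchronous stroking — is `beta1 + beta3 * CIA_i + r_i`, with
#' `r_i ~ Normal(0, sigma_r^2)` the unexplained individual deviation.
#' The latent residual SD is fixed at 1 (probit identification); there is
#' no intercept, fixed or random — location is carried entirely by the
#' K - 1 ordered cutpoints.
#'
#' @param beta1 Fixed condition effect (latent-probit units).
#' @param beta2 CIA main effect (baseline modulation).
#' @param beta3 Condition x CIA interaction: the slope of the implicit
#'   regression of susceptibility on CIA.
#' @param sigma_r SD of the random condition slopes (> 0).
#' @param r Numeric vector of N per-participant slope deviations.
#' @param cutpoints Strictly increasing numeric vector of K - 1
#'   thresholds.
#' @return An object of class `rhi_params`.
#' @export
model_parameters <- function(beta1, beta2, beta3, sigma_r, r, cutpoints) {
  if (!is.numeric(sigma_r) || length(sigma_r) != 1L || sigma_r <= 0) {
    stop("sigma_r must be a single positive number")
  }
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 2L || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be strictly increasing (length K - 1 >= 2)")
  }
  structure(
    list(beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
         beta3 = as.numeric(beta3), sigma_r = as.numeric(sigma_r),
         r = as.numeric(r), cutpoints = cutpoints),
    class = "rhi_params"
  )
}

#' Latent-scale linear predictor
#'
#' Evaluates `eta = (beta1 + r_i) * cond + beta2 * cia + beta3 * cond * cia`
#' for one participant and condition. At `cond = 0` all slope terms vanish
#' and only the CIA baseline term remains.
#'
#' @param params An `rhi_params` object (see [model_parameters()]).
#' @param cia CIA score of the participant.
#' @param cond Condition code: 0 (asynchronous) or 1 (synchronous).
#' @param i Participant index into `params$r`.
#' @return The latent mean `eta` (the residual is excluded).
#' @export
linear_predictor <- function(params, cia, cond, i) {
  if (i < 1L || i > length(params$r)) stop("participant index out of range")
  if (!cond %in% c(0, 1)) stop("cond must be 0 or 1")
  (params$beta1 + params$r[i]) * cond + params$beta2 * cia +
    params$beta3 * cond * cia
}

#' Ordinal category probabilities under the probit link
#'
#' `P(Y = k) = pnorm(tau_k - eta) - pnorm(tau_{k-1} - eta)` with
#' `tau_0 = -Inf` and `tau_K = +Inf`. The probabilities telescope to 1 for
#' any latent mean and any strictly increasing cutpoints.
#'
#' @param eta Latent mean (scalar).
#' @param cutpoints Strictly increasing numeric vector of K - 1
#'   thresholds.
#' @return Numeric probability vector of length K.
#' @export
category_probs <- function(eta, cutpoints) {
  cutpoints <- as.numeric(cutpoints)
  if (any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be strictly increasing")
  }
  normal_band_prob(c(-Inf, cutpoints) - eta, c(cutpoints, Inf) - eta)
}

# P(lo < Z <= hi) for standard-normal Z, computed through the tail that
# avoids cancellation: when both bounds sit in the upper tail the naive
# pnorm(hi) - pnorm(lo) subtracts two numbers near 1 and loses all
# relative accuracy on small band probabilities.
normal_band_prob <- function(lo, hi) {
  pmax(ifelse(lo > 0,
              stats::pnorm(lo, lower.tail = FALSE) -
                stats::pnorm(hi, lower.tail = FALSE),
              stats::pnorm(hi) - stats::pnorm(lo)),
       0)
}

# Floor applied to category probabilities before taking logs, so that a
# category far in the tail yields a very negative but finite contribution.
PROB_FLOOR <- 1e-300

# Vectorized log P(Y = y | eta) for observed categories y (1..K).
obs_log_prob <- function(y, eta, cutpoints) {
  hi <- c(cutpoints, Inf)[y]
  lo <- c(-Inf, cutpoints)[y]
  log(pmax(normal_band_prob(lo - eta, hi - eta), PROB_FLOOR))
}

# Latent means for all participants under each condition.
eta_async <- function(params, data) params$beta2 * data$cia
eta_sync <- function(params, data) {
  params$beta1 + params$r + (params$beta2 + params$beta3) * data$cia
}

#' Model log-likelihood
#'
#' Sum over all (participant, condition) observations of the log
#' probability of the observed ordinal category given the latent mean.
#' Probabilities are floored at `1e-300` before the log so that extreme
#' parameter values give a finite (very negative) value rather than
#' `-Inf` from underflow.
#'
#' @param params An `rhi_params` object dimensioned for `data`
#'   (N random slopes, K - 1 cutpoints).
#' @param data An `rhi_data` object (see [assemble_dataset()]).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, data) {
  n <- length(data$participants)
  if (length(params$r) != n) {
    stop("params$r has length ", length(params$r), " but data has ", n,
         " participants")
  }
  if (length(params$cutpoints) != data$n_categories - 1L) {
    stop("params has ", length(params$cutpoints),
         " cutpoints but data declares K = ", data$n_categories)
  }
  sum(obs_log_prob(data$ratings[, "async"], eta_async(params, data),
                   params$cutpoints)) +
    sum(obs_log_prob(data$ratings[, "sync"], eta_sync(params, data),
                     params$cutpoints))
}

#' Model log-prior
#'
#' Sum of the log prior densities: the coefficient prior on each of
#' beta1, beta2, beta3; the SD prior on sigma_r; `Normal(0, sigma_r)` on
#' each random slope `r_i`; and the cutpoint prior on each threshold
#' (the ordering constraint is enforced structurally by the sampler, not
#' by the prior).
#'
#' @inheritParams log_likelihood
#' @param prior An `rhi_prior` object (see [prior_config()]).
#' @return Scalar log prior density; `-Inf` if `sigma_r <= 0`.
#' @export
log_prior <- function(params, prior) {
  if (params$sigma_r <= 0) return(-Inf)
  coef_lp <- sum(ls_log_density(c(params$beta1, params$beta2, params$beta3),
                                prior$coef$family, prior$coef$location,
                                prior$coef$scale, prior$coef$df))
  sigma_lp <- sigma_log_density(params$sigma_r, prior$sigma$family,
                                prior$sigma$scale, prior$sigma$df)
  r_lp <- sum(stats::dnorm(params$r, 0, params$sigma_r, log = TRUE))
  tau_lp <- sum(ls_log_density(params$cutpoints, prior$cutpoint$family,
                               prior$cutpoint$location, prior$cutpoint$scale,
                               prior$cutpoint$df))
  coef_lp + sigma_lp + r_lp + tau_lp
}

#' Unnormalized log-posterior
#'
#' `log_likelihood + log_prior`; the likelihood can be switched off to
#' target the prior alone (useful for prior-recovery checks of the
#' sampler).
#'
#' @inheritParams log_prior
#' @param include_likelihood Logical; if `FALSE` only the prior enters.
#' @return Scalar unnormalized log posterior density.
#' @export
log_posterior <- function(params, data, prior, include_likelihood = TRUE) {
  lp <- log_prior(params, prior)
  if (include_likelihood) lp <- lp + log_likelihood(params, data)
  lp
}
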