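#' Per-participant susceptibility draws
#'
#' A participant's illusion susceptibility is the individual effect of
#' synchronous (vs asynchronous) stroking on the latent ownership scale:
#' `s_i = beta1 + beta3 * CIA_i + r_i`. This evaluates it for every
#' posterior draw and participant.
#'
#' @param draws An `rhi_draws` object.
#' @param data The `rhi_data` object the draws were fitted to.
#' @return Numeric M x N matrix (draws x participants), columns named by
#'   participant identifier.
#' @export
susceptibility_draws <- function(draws, data) {
  pids <- data$participants
  rcols <- paste0("r_", pids)
  missing_r <- setdiff(rcols, names(draws))
  if (length(missing_r) > 0L) {
    stop("draws lack random-slope column(s) for participant(s): ",
         paste(sub("^r_", "", missing_r), collapse = ", "))
  }
  r <- as.matrix(draws[, rcols, drop = FALSE])
  s <- draws$beta1 + outer(draws$beta3, as.numeric(data$cia)) + r
  colnames(s) <- pids
  s
}

#' Summarize per-participant susceptibility
#'
#' Posterior median and 95% equal-tailed credible interval of each
#' participant's susceptibility, with a flag for whether the interval
#' includes 0 (a participant whose interval excludes 0 unambiguously
#' experienced the ownership shift).
#'
#' @inheritParams susceptibility_draws
#' @param mass Interval mass (default 0.95).
#' @return Data frame with columns `participant`, `cia`, `median`,
#'   `lower`, `upper`, `includes_zero`.
#' @export
susceptibility_summary <- function(draws, data, mass = 0.95) {
  s <- susceptibility_draws(draws, data)
  lo <- (1 - mass) / 2
  q <- apply(s, 2L, stats::quantile, probs = c(lo, 1 - lo))
  out <- data.frame(
    participant = data$participants,
    cia = as.numeric(data$cia),
    median = apply(s, 2L, stats::median),
    lower = q[1L, ],
    upper = q[2L, ],
    stringsAsFactors = FALSE
  )
  out$includes_zero <- out$lower <= 0 & out$upper >= 0
  rownames(out) <- NULL
  out
}

#' Count participants whose susceptibility interval includes zero
#'
#' @param summaries Data frame from [susceptibility_summary()].
#' @return List with `n_including`, `n_excluding` and `n_total`.
#' @export
count_includes_zero <- function(summaries) {
  n_inc <- sum(summaries$includes_zero)
  list(n_including = n_inc,
       n_excluding = nrow(summaries) - n_inc,
       n_total = nrow(summaries))
}

#' Standardized interaction effect size
#'
#' The interaction coefficient scaled by the random-slope SD,
#' `beta3 / sigma_r`, computed per posterior draw. In the spirit of
#' Cohen's d, it is the standardized difference between the mean
#' susceptibilities of a hypothetical population with CIA = 0 (unable to
#' perceive their heartbeat) and one with CIA = 1 (perfect perception),
#' with the unexplained inter-individual SD as the unit.
#'
#' @param draws An `rhi_draws` object containing `beta3` and `sigma_r`.
#' @param mass Interval mass (default 0.95, equal-tailed).
#' @return Data frame (one row) with columns `name`, `median`, `lower`,
#'   `upper`, `mass`, `interval_type`, plus attribute `draws` holding the
#'   per-draw values.
#' @export
standardized_beta3 <- function(draws, mass = 0.95) {
  val <- draws$beta3 / draws$sigma_r
  ci <- unname(stats::quantile(val, c((1 - mass) / 2, 1 - (1 - mass) / 2)))
  structure(
    data.frame(name = "standardized_beta3", median = stats::median(val),
               lower = ci[1L], upper = ci[2L], mass = mass,
               interval_type = "equal_tailed", stringsAsFactors = FALSE),
    draws = val
  )
}

#' Bayesian R-squared for the susceptibility regression
#'
#' Per posterior draw, the proportion of variance in susceptibility
#' explained by CIA: `V_fit / (V_fit + V_res)` where `V_fit` is the
#' sample variance (denominator N - 1) of the fitted values
#' `beta3 * CIA_i` over participants and `V_res` is the modelled residual
#' variance `sigma_r^2`. Each per-draw value lies in `[0, 1]`; the
#' summary is the posterior median with a 95% HPDI, whose lower end sits
#' essentially at zero whenever the interaction is consistent with zero.
#' With all CIA values identical, `V_fit = 0` and the statistic is
#' identically 0.
#'
#' @inheritParams susceptibility_draws
#' @param mass Interval mass (default 0.95, HPDI).
#' @param residual `"sigma"` (default) uses the model-based residual
#'   variance `sigma_r^2`; `"empirical"` uses the per-draw sample
#'   variance of the realized random slopes instead.
#' @return Data frame (one row) as in [standardized_beta3()], with
#'   `interval_type = "hpdi"` and per-draw values in attribute `draws`.
#' @export
bayes_r2 <- function(draws, data, mass = 0.95,
                     residual = c("sigma", "empirical")) {
  residual <- match.arg(residual)
  cia <- as.numeric(data$cia)
  if (length(cia) < 2L) stop("Bayesian R-squared requires N >= 2")
  v_fit <- draws$beta3^2 * stats::var(cia)
  v_res <- if (residual == "sigma") {
    draws$sigma_r^2
  } else {
    r <- as.matrix(draws[, paste0("r_", data$participants), drop = FALSE])
    apply(r, 1L, stats::var)
  }
  val <- ifelse(v_fit == 0, 0, v_fit / (v_fit + v_res))
  ci <- hpdi(val, mass)
  structure(
    data.frame(name = "bayes_r2", median = stats::median(val),
               lower = ci[1L], upper = ci[2L], mass = mass,
               interval_type = "hpdi", stringsAsFactors = FALSE),
    draws = val
  )
}

#' Full analysis report
#'
#' Assembles the three reporting tables: (1) posterior medians and 95%
#' equal-tailed credible intervals of the four focal parameters
#' `beta1, sigma_r, beta2, beta3`; (2) the two effect sizes (standardized
#' interaction with equal-tailed interval, Bayesian R-squared with HPDI);
#' (3) per-participant susceptibility with the includes-zero
#' classification and its counts. A warning is issued when any focal
#' parameter fails the R-hat gate.
#'
#' @inheritParams susceptibility_draws
#' @param rhat_threshold Convergence threshold for the warning
#'   (default 1.1).
#' @return An object of class `rhi_report`: list with elements
#'   `parameters`, `effects`, `susceptibility` (data frames), `counts`
#'   (from [count_includes_zero()]) and `convergence`.
#' @export
make_report <- function(draws, data, rhat_threshold = 1.1) {
  focal <- intersect(c("beta1", "sigma_r", "beta2", "beta3"), names(draws))
  conv <- convergence_report(draws, threshold = rhat_threshold,
                             parameters = focal)
  if (!attr(conv, "overall_pass")) {
    warning("R-hat exceeds ", rhat_threshold, " for: ",
            paste(conv$parameter[!conv$pass], collapse = ", "),
            "; treat the report as unconverged")
  }
  params <- summarize_posterior(draws, focal)
  effects <- rbind(
    as.data.frame(standardized_beta3(draws)),
    as.data.frame(bayes_r2(draws, data))
  )
  susc <- susceptibility_summary(draws, data)
  structure(
    list(parameters = params, effects = effects, susceptibility = susc,
         counts = count_includes_zero(susc), convergence = conv),
    class = "rhi_report"
  )
}

#' @export
print.rhi_report <- function(x, digits = 3, ...) {
  cat("== Parameter summary (posterior median, 95% CrI) ==\n")
  p <- x$parameters
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-8s %6.*f  [%.*f, %.*f]\n", p$parameter[i],
                digits, p$median[i], digits, p$lower[i], digits,
                p$upper[i]))
  }
  cat("== Effect sizes ==\n")
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-20s %6.*f  [%.3g, %.3g] (%s)\n", e$name[i],
                digits, e$median[i], e$lower[i], e$upper[i],
                e$interval_type[i]))
  }
  cat("== Susceptibility ==\n")
  cat(sprintf("  %d of %d participants include 0 in the 95%% CrI (%d exclude it)\n",
              x$counts$n_including, x$counts$n_total, x$counts$n_excluding))
  invisible(x)
}

#' Susceptibility-versus-CIA figure
#'
#' Plots each participant's posterior median susceptibility (point) and
#' 95% credible interval (vertical segment) against CIA, colored by
#' whether the interval includes zero. A downward trend of the points
#' would indicate negative modulation of susceptibility by CIA.
#'
#' @param summaries Data frame from [susceptibility_summary()].
#' @return A `ggplot` object.
#' @export
plot_susceptibility <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_susceptibility requires the ggplot2 package")
  }
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = cia, y = median,
                               color = includes_zero)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = lower, ymax = upper)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#4477AA", `FALSE` = "#EE7733"),
      labels = c(`TRUE` = "CrI includes 0", `FALSE` = "CrI excludes 0"),
      name = NULL) +
    ggplot2::labs(x = "Cardiac interoceptive accuracy",
                  y = "Estimated susceptibility (latent probit scale)") +
    ggplot2::theme_minimal()
}
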