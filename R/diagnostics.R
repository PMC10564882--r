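#' Split-chain potential scale reduction factor (R-hat)
#'
#' Computes R-hat for one parameter by splitting every chain in half and
#' comparing between-half and within-half variance. The default
#' `"rank_normalized"` variant ranks the pooled draws, maps the ranks
#' through the normal quantile function, and takes the larger of the
#' bulk statistic (on the rank-normal scores) and the folded statistic
#' (on scores of absolute deviations from the median), making the
#' diagnostic robust to heavy tails and scale differences. `"classic"`
#' computes split R-hat on the raw draws. Values near 1 indicate that the
#' chains have mixed; the conventional acceptance rule used here is
#' R-hat <= 1.1.
#'
#' Chains that are all identical and constant are degenerate for the
#' variance ratio; R-hat is returned as 1 by convention in that case.
#'
#' @param draws An `rhi_draws` object (>= 2 chains, >= 4 draws per chain).
#' @param parameter Parameter name (a column of `draws`).
#' @param method `"rank_normalized"` (default) or `"classic"`.
#' @return Scalar R-hat.
#' @export
rhat <- function(draws, parameter, method = c("rank_normalized", "classic")) {
  method <- match.arg(method)
  if (!parameter %in% names(draws)) {
    stop("unknown parameter: ", parameter)
  }
  chains <- split(draws[[parameter]], draws$.chain)
  if (length(chains) < 2L) stop("R-hat requires at least 2 chains")
  len <- unique(vapply(chains, length, integer(1)))
  if (length(len) != 1L) stop("chains must have equal length")
  if (len < 4L) stop("R-hat requires at least 4 draws per chain")
  mat <- do.call(cbind, chains)       # iterations x chains
  half <- floor(nrow(mat) / 2L)
  splitmat <- cbind(mat[seq_len(half), , drop = FALSE],
                    mat[nrow(mat) - half + seq_len(half), , drop = FALSE])
  if (method == "classic") {
    return(rhat_from_matrix(splitmat))
  }
  bulk <- rhat_from_matrix(rank_normalize(splitmat))
  folded <- rhat_from_matrix(
    rank_normalize(abs(splitmat - stats::median(splitmat)))
  )
  max(bulk, folded)
}

# Split R-hat on an iterations x chains matrix; 1 by convention when the
# within-chain variance is exactly zero everywhere.
rhat_from_matrix <- function(mat) {
  m <- ncol(mat)
  n <- nrow(mat)
  means <- colMeans(mat)
  vars <- apply(mat, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# Rank-normalize a matrix of draws jointly (fractional ranks with the
# Blom offset mapped through qnorm), preserving the matrix layout.
rank_normalize <- function(mat) {
  s <- length(mat)
  z <- stats::qnorm((rank(mat, ties.method = "average") - 3 / 8) /
                      (s + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted draws containing
#' `ceiling(mass * M)` of the M draws; ties in width are broken to the
#' leftmost window.
#'
#' @param samples Numeric vector of draws (length >= 2).
#' @param mass Probability mass in (0, 1) (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(samples, mass = 0.95) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("hpdi requires at least 2 samples")
  if (!is.finite(mass) || mass <= 0 || mass >= 1) {
    stop("mass must lie strictly between 0 and 1")
  }
  s <- sort(samples)
  m <- ceiling(mass * length(s))
  if (m >= length(s)) return(c(s[1L], s[length(s)]))
  widths <- s[seq(m, length(s))] - s[seq_len(length(s) - m + 1L)]
  j <- which.min(widths)  # leftmost minimum
  c(s[j], s[j + m - 1L])
}

#' Summarize posterior draws of one or more parameters
#'
#' Posterior median plus a 95% (by default) interval: either the
#' equal-tailed credible interval from symmetric empirical quantiles
#' (used for the regression coefficients, the random-slope SD and the
#' per-participant susceptibilities) or the highest posterior density
#' interval (used for the Bayesian R-squared, whose posterior piles up
#' near zero).
#'
#' @param draws An `rhi_draws` object, or a data frame of draws.
#' @param parameters Character vector of parameter names; default all
#'   sampled parameters.
#' @param mass Interval probability mass (default 0.95).
#' @param interval_type `"equal_tailed"` (default) or `"hpdi"`.
#' @return Data frame with columns `parameter`, `median`, `lower`,
#'   `upper`, `mass`, `interval_type`.
#' @export
summarize_posterior <- function(draws, parameters = NULL, mass = 0.95,
                                interval_type = c("equal_tailed", "hpdi")) {
  interval_type <- match.arg(interval_type)
  if (is.null(parameters)) {
    parameters <- setdiff(names(draws), c(".chain", ".iteration"))
  }
  missing_p <- setdiff(parameters, names(draws))
  if (length(missing_p) > 0L) {
    stop("unknown parameter(s): ", paste(missing_p, collapse = ", "))
  }
  rows <- lapply(parameters, function(p) {
    x <- draws[[p]]
    ci <- if (interval_type == "hpdi") hpdi(x, mass) else
      unname(stats::quantile(x, c((1 - mass) / 2, 1 - (1 - mass) / 2)))
    data.frame(parameter = p, median = stats::median(x),
               lower = ci[1L], upper = ci[2L], mass = mass,
               interval_type = interval_type, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Convergence report over all (or selected) parameters
#'
#' Computes R-hat per parameter and flags every parameter exceeding the
#' threshold; the overall run passes iff none do. An empty parameter
#' selection yields an empty report that passes vacuously.
#'
#' @param draws An `rhi_draws` object.
#' @param threshold R-hat acceptance threshold (default 1.1).
#' @param parameters Parameters to check (default: all sampled).
#' @param method R-hat variant, passed to [rhat()].
#' @return An object of class `rhi_convergence`: data frame with columns
#'   `parameter`, `rhat`, `pass`, and attributes `overall_pass` and
#'   `threshold`.
#' @export
convergence_report <- function(draws, threshold = 1.1, parameters = NULL,
                               method = c("rank_normalized", "classic")) {
  method <- match.arg(method)
  if (is.null(parameters)) parameters <- parameter_names(draws)
  rh <- vapply(parameters, function(p) rhat(draws, p, method), numeric(1))
  out <- data.frame(parameter = parameters,
                    rhat = unname(rh),
                    pass = unname(rh <= threshold),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            class = c("rhi_convergence", "data.frame"),
            overall_pass = all(out$pass),
            threshold = threshold)
}

#' @export
print.rhi_convergence <- function(x, ...) {
  cat("<rhi_convergence> ", nrow(x), " parameter(s), threshold R-hat <= ",
      attr(x, "threshold"), "\n", sep = "")
  if (nrow(x) == 0L) {
    cat("  empty selection: pass (vacuous)\n")
  } else if (attr(x, "overall_pass")) {
    cat("  overall: PASS (max R-hat = ", signif(max(x$rhat), 4), ")\n",
        sep = "")
  } else {
    bad <- x$parameter[!x$pass]
    cat("  overall: FAIL; exceeding parameters: ",
        paste(bad, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Long-format trace data for plotting
#'
#' @param draws An `rhi_draws` object.
#' @param parameters Parameters to extract (default: the four focal
#'   parameters present in the draws).
#' @return Data frame with columns `parameter`, `chain`, `iteration`,
#'   `value`, suitable for trace plots.
#' @export
trace_data <- function(draws, parameters = NULL) {
  if (is.null(parameters)) {
    parameters <- intersect(c("beta1", "beta2", "beta3", "sigma_r"),
                            names(draws))
  }
  rows <- lapply(parameters, function(p) {
    data.frame(parameter = p, chain = draws$.chain,
               iteration = draws$.iteration, value = draws[[p]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
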