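#' Configuration of the synthetic-data generator
#'
#' The generator realizes exactly the statistical structure the model
#' assumes: per-participant CIA drawn from a distribution on `[0, 1]`,
#' a random condition slope `r_i ~ Normal(0, sigma_r^2)`, a latent
#' ownership intensity
#' `eta + epsilon` with standard-normal residual, and ordered cutpoints
#' discretizing the latent value into K categories — one rating per
#' participant per condition.
#'
#' Defaults emulate a typical heartbeat-tracking sample: CIA is
#' Beta(5, 2.7) (mean about 0.65, most mass between 0.3 and 0.95), and
#' the K = 7 cutpoints are symmetric and unit-spaced on the latent scale.
#'
#' @param n_participants Number of participants N (>= 2).
#' @param beta1,beta2,beta3 True regression coefficients (condition
#'   effect, CIA main effect, interaction).
#' @param sigma_r True SD of the random condition slopes (>= 0; zero
#'   gives identical susceptibility `beta1 + beta3 * CIA_i` for all).
#' @param cutpoints Strictly increasing vector of K - 1 thresholds
#'   (default the symmetric 7-category set -2.5 .. 2.5).
#' @param cia_shape1,cia_shape2 Beta shape parameters of the CIA
#'   distribution. Set `cia_fixed` to override with a constant.
#' @param cia_fixed Optional scalar or length-N vector of fixed CIA
#'   values (degenerate distribution for edge-case checks).
#' @param seed Integer seed; identical configurations reproduce
#'   identical datasets.
#' @return An object of class `rhi_generator_config`.
#' @export
generator_config <- function(n_participants, beta1 = 0.5, beta2 = 0.25,
                             beta3 = 0.33, sigma_r = 2.2,
                             cutpoints = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
                             cia_shape1 = 5, cia_shape2 = 2.7,
                             cia_fixed = NULL, seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (n_participants < 2L) stop("n_participants must be >= 2")
  if (sigma_r < 0) stop("sigma_r must be >= 0")
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 2L || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be strictly increasing with length K - 1 >= 2")
  }
  structure(
    list(n_participants = n_participants, beta1 = beta1, beta2 = beta2,
         beta3 = beta3, sigma_r = sigma_r, cutpoints = cutpoints,
         cia_shape1 = cia_shape1, cia_shape2 = cia_shape2,
         cia_fixed = cia_fixed, seed = as.integer(seed)),
    class = "rhi_generator_config"
  )
}

#' Simulate an analysis dataset from the generative model
#'
#' Draws `CIA_i` and `r_i`, forms the latent means
#' `eta_{i,0} = beta2 * CIA_i` and
#' `eta_{i,1} = beta1 + r_i + (beta2 + beta3) * CIA_i`, adds
#' standard-normal residuals, and cuts the latent values at the
#' cutpoints: the rating is category k when the latent value falls in
#' `(tau_{k-1}, tau_k]`. Deterministic under a fixed seed.
#'
#' @param config An `rhi_generator_config` object.
#' @return An `rhi_data` object (participants `P001`, `P002`, ...) with
#'   attribute `truth`: a list holding the true parameters and a data
#'   frame of per-participant `cia`, `r`, `eta_async`, `eta_sync`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "rhi_generator_config"))
  set.seed(config$seed)
  n <- config$n_participants
  K <- length(config$cutpoints) + 1L
  ids <- sprintf("P%03d", seq_len(n))
  cia <- if (!is.null(config$cia_fixed)) {
    rep_len(as.numeric(config$cia_fixed), n)
  } else {
    stats::rbeta(n, config$cia_shape1, config$cia_shape2)
  }
  r <- stats::rnorm(n, 0, config$sigma_r)
  eta0 <- config$beta2 * cia
  eta1 <- config$beta1 + r + (config$beta2 + config$beta3) * cia
  cut_at <- function(latent) {
    findInterval(latent, config$cutpoints, left.open = TRUE) + 1L
  }
  y0 <- cut_at(eta0 + stats::rnorm(n))
  y1 <- cut_at(eta1 + stats::rnorm(n))
  ratings <- cbind(async = y0, sync = y1)
  rownames(ratings) <- ids
  structure(
    list(participants = ids,
         cia = stats::setNames(cia, ids),
         ratings = ratings,
         n_categories = K),
    class = "rhi_data",
    truth = list(beta1 = config$beta1, beta2 = config$beta2,
                 beta3 = config$beta3, sigma_r = config$sigma_r,
                 cutpoints = config$cutpoints,
                 latent = data.frame(participant = ids, cia = cia, r = r,
                                     eta_async = eta0, eta_sync = eta1,
                                     stringsAsFactors = FALSE))
  )
}

#' Simulate heartbeat-tracking trials hitting target CIA scores
#'
#' Inverts the CIA formula: the recorded count of each trial is the
#' rounded expected beat count at the given heart rate, and the reported
#' count is the integer whose per-trial accuracy
#' `1 - |recorded - reported| / recorded` is closest to the target
#' (ties broken to the under-reporting side). Because counts are
#' integers, the achieved CIA matches the target only up to rounding;
#' the discrepancy is bounded by `0.5 / min(recorded)` per trial.
#'
#' @param participant_targets Named numeric vector of target CIA values
#'   in `[0, 1]` (names are participant identifiers).
#' @param durations Trial durations in seconds (default 25, 35, 45).
#' @param heart_rate_bpm Heart rate in beats per minute (default 70).
#' @param seed Unused randomness placeholder kept for interface symmetry;
#'   the construction is deterministic.
#' @return Data frame of heartbeat trials (three per participant) in the
#'   layout of [read_heartbeat_trials()].
#' @export
simulate_heartbeat_trials <- function(participant_targets,
                                      durations = c(25, 35, 45),
                                      heart_rate_bpm = 70, seed = 1L) {
  if (is.null(names(participant_targets))) {
    names(participant_targets) <-
      sprintf("P%03d", seq_along(participant_targets))
  }
  if (any(participant_targets < 0 | participant_targets > 1)) {
    stop("target CIA values must lie in [0, 1]")
  }
  if (length(durations) != 3L) stop("exactly 3 trial durations required")
  rec <- pmax(1L, as.integer(round(heart_rate_bpm * durations / 60)))
  rows <- lapply(names(participant_targets), function(id) {
    target <- participant_targets[[id]]
    rep_ <- vapply(rec, function(rc) {
      # candidate reported counts on both sides of the exact solution
      offset <- rc * (1 - target)
      cand <- unique(pmax(0L, c(floor(rc - offset), ceiling(rc - offset),
                                floor(rc + offset), ceiling(rc + offset))))
      achieved <- 1 - abs(rc - cand) / rc
      err <- abs(achieved - target)
      best <- cand[err == min(err)]
      as.integer(min(best))  # under-reporting preferred on ties
    }, integer(1))
    data.frame(participant = id, trial = seq_len(3L),
               duration_s = durations, hb_recorded = rec,
               hb_reported = rep_, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a simulated dataset to the native CSV formats
#'
#' Convenience wrapper emitting the ratings CSV, the CIA CSV and, when
#' `truth_path` is given, a truth CSV with the per-participant latent
#' record for recovery checks.
#'
#' @param data An `rhi_data` object from [simulate_dataset()].
#' @param ratings_path,cia_path,truth_path Output paths (`truth_path`
#'   optional).
#' @param scale_min Printed scale minimum used to de-shift categories
#'   (default `-(K - 1) / 2` for odd K, i.e. -3 for K = 7, otherwise 1).
#' @return Invisibly, a character vector of the files written.
#' @export
write_simulated_dataset <- function(data, ratings_path, cia_path,
                                    truth_path = NULL, scale_min = NULL) {
  K <- data$n_categories
  if (is.null(scale_min)) {
    scale_min <- if (K %% 2L == 1L) -(K - 1L) / 2L else 1L
  }
  recs <- data.frame(
    participant = rep(data$participants, 2L),
    condition = rep(c(0L, 1L), each = length(data$participants)),
    item = 3L,
    rating_raw = c(data$ratings[, "async"], data$ratings[, "sync"]) +
      as.integer(scale_min) - 1L,
    stringsAsFactors = FALSE
  )
  write_ratings(recs, ratings_path)
  write_cia_scores(data.frame(participant = data$participants,
                              cia = as.numeric(data$cia)), cia_path)
  written <- c(ratings_path, cia_path)
  truth <- attr(data, "truth")
  if (!is.null(truth_path) && !is.null(truth)) {
    utils::write.csv(truth$latent, truth_path, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    written <- c(written, truth_path)
  }
  invisible(written)
}
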