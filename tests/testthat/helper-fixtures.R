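# Shared fixture builders for the test suite. All fixtures are generated
# in code; nothing is read from disk except files the tests themselves
# write to tempdir().

# Minimal ratings data frame on the -3..+3 scale: one row per
# participant x condition for the ownership item.
make_ratings_df <- function(ids = c("a", "b"), async = c(-1, 0),
                            sync = c(2, 1), item = 3L) {
  data.frame(
    participant = rep(ids, 2L),
    condition = rep(c("async", "sync"), each = length(ids)),
    item = item,
    rating = c(async, sync),
    stringsAsFactors = FALSE
  )
}

write_ratings_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A small well-formed heartbeat-trial table.
make_heartbeat_df <- function(ids = c("a", "b"),
                              rec = c(30, 40, 50),
                              rep_ = c(28, 40, 47)) {
  do.call(rbind, lapply(ids, function(id) {
    data.frame(participant = id, trial = 1:3,
               duration_s = c(25, 35, 45),
               hb_recorded = rec, hb_reported = rep_,
               stringsAsFactors = FALSE)
  }))
}

# Hand-built draws object with known values for effect-size arithmetic.
make_draws <- function(beta1, beta2, beta3, sigma_r, r_mat, cutpoints_mat,
                       n_chains = 2L) {
  m <- length(beta1)
  stopifnot(m %% n_chains == 0L)
  pids <- colnames(r_mat)
  df <- data.frame(.chain = rep(seq_len(n_chains), each = m / n_chains),
                   .iteration = rep(seq_len(m / n_chains), n_chains),
                   beta1 = beta1, beta2 = beta2, beta3 = beta3,
                   sigma_r = sigma_r, check.names = FALSE)
  for (k in seq_len(ncol(cutpoints_mat))) {
    df[[paste0("tau_", k)]] <- cutpoints_mat[, k]
  }
  for (j in seq_along(pids)) df[[paste0("r_", pids[j])]] <- r_mat[, j]
  structure(df, class = c("rhi_draws", "data.frame"),
            participants = pids,
            n_categories = ncol(cutpoints_mat) + 1L,
            mcmc_config = mcmc_config(n_chains = n_chains,
                                      n_iterations = m / n_chains + 1L,
                                      n_warmup = 1L, seed = 0L),
            parameterization = "noncentered")
}

# Small rhi_data built directly (bypassing file IO) for model tests.
make_data <- function(cia, y_async, y_sync, K = 7L) {
  ids <- sprintf("P%03d", seq_along(cia))
  ratings <- cbind(async = as.integer(y_async), sync = as.integer(y_sync))
  rownames(ratings) <- ids
  structure(list(participants = ids,
                 cia = stats::setNames(as.numeric(cia), ids),
                 ratings = ratings,
                 n_categories = as.integer(K)),
            class = "rhi_data")
}

# Random valid parameter set for a given data dimension.
random_params <- function(n, K, rng_scale = 1) {
  model_parameters(beta1 = rnorm(1, 0, rng_scale),
                   beta2 = rnorm(1, 0, rng_scale),
                   beta3 = rnorm(1, 0, rng_scale),
                   sigma_r = rexp(1) + 0.2,
                   r = rnorm(n, 0, rng_scale),
                   cutpoints = sort(rnorm(K - 1L, 0, 1.5)) +
                     seq(0, (K - 2L) * 1e-3, length.out = K - 1L))
}
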