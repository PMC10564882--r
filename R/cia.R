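#' Cardiac interoceptive accuracy from heartbeat-tracking trials
#'
#' Scores the heartbeat tracking task for one participant. Each of the
#' three trials contributes an accuracy term
#' `1 - |recorded - reported| / recorded`, and the CIA score is their
#' arithmetic mean. A perfect reporter scores 1; reporting zero beats on
#' every trial scores 0. Over-reporting beyond twice the recorded count
#' drives a term below zero: such scores are retained (not clamped) and
#' flagged, because the formula itself does not enforce the nominal
#' `[0, 1]` range. Set `clamp = TRUE` to truncate the final score into
#' `[0, 1]` for sensitivity checks.
#'
#' Trial durations play no role in the score; only the counts enter.
#'
#' @param trials Data frame of exactly three rows for one participant with
#'   columns `hb_recorded` (>= 1) and `hb_reported` (>= 0); a
#'   `participant` column, if present, must hold a single identifier.
#' @param clamp Logical; truncate the score to `[0, 1]` (default `FALSE`).
#' @return An object of class `cia_score`: list with `participant_id`,
#'   `per_trial_accuracy` (length 3), `cia` (their mean) and
#'   `out_of_range_flag` (`TRUE` iff the unclamped score falls outside
#'   `[0, 1]`).
#' @examples
#' trials <- data.frame(hb_recorded = c(40, 50, 60),
#'                      hb_reported = c(30, 45, 66))
#' compute_cia(trials)$cia  # (0.75 + 0.90 + 0.90) / 3 = 0.85
#' @export
compute_cia <- function(trials, clamp = FALSE) {
  if (nrow(trials) != 3L) {
    stop("a CIA score requires exactly 3 trials; got ", nrow(trials))
  }
  pid <- if ("participant" %in% names(trials)) {
    ids <- unique(as.character(trials$participant))
    if (length(ids) != 1L) stop("trials belong to more than one participant")
    ids
  } else NA_character_
  rec <- as.numeric(trials$hb_recorded)
  rep_ <- as.numeric(trials$hb_reported)
  if (any(rec < 1)) stop("hb_recorded must be >= 1 on every trial")
  if (any(rep_ < 0)) stop("hb_reported must be non-negative")
  acc <- 1 - abs(rec - rep_) / rec
  cia <- mean(acc)
  flag <- cia < 0 || cia > 1
  if (clamp) cia <- min(max(cia, 0), 1)
  structure(
    list(participant_id = pid,
         per_trial_accuracy = acc,
         cia = cia,
         out_of_range_flag = flag),
    class = "cia_score"
  )
}

#' @export
print.cia_score <- function(x, ...) {
  cat("<cia_score>", if (!is.na(x$participant_id)) x$participant_id else "",
      " cia = ", signif(x$cia, 4),
      if (x$out_of_range_flag) "  [outside 0..1]" else "", "\n", sep = "")
  invisible(x)
}

#' Score the heartbeat tracking task for every participant
#'
#' Applies [compute_cia()] per participant over a trial table. Participants
#' without exactly three trials are dropped with a warning (their score is
#' undefined).
#'
#' @param trials Data frame as returned by [read_heartbeat_trials()].
#' @inheritParams compute_cia
#' @return Data frame with columns `participant`, `cia` and `flag`
#'   (score outside `[0, 1]` before any clamping), sorted by participant.
#' @export
cia_scores <- function(trials, clamp = FALSE) {
  ids <- sort(unique(trials$participant))
  counts <- table(trials$participant)
  bad <- names(counts)[counts != 3L]
  if (length(bad) > 0L) {
    warning("dropping participant(s) without exactly 3 trials: ",
            paste(bad, collapse = ", "))
    ids <- setdiff(ids, bad)
  }
  rows <- lapply(ids, function(id) {
    s <- compute_cia(trials[trials$participant == id, , drop = FALSE],
                     clamp = clamp)
    data.frame(participant = id, cia = s$cia, flag = s$out_of_range_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(participant = character(), cia = numeric(),
                      flag = logical())
  }
  out
}
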