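#' Read Likert-type ratings from a delimited file
#'
#' Reads one ordinal rating per participant x condition (x item) from a CSV
#' file with header columns `participant`, `condition`, `item`, `rating`.
#' Condition labels are normalized to the internal binary coding
#' 0 = asynchronous, 1 = synchronous; accepted spellings are `0`/`1`,
#' `async`/`sync` and `asynchronous`/`synchronous` (case-insensitive).
#' Raw ratings on the instrument's printed scale (`scale_min`..`scale_max`,
#' e.g. -3..+3 for a 7-point item) are shifted to internal categories
#' `1..K` with `K = scale_max - scale_min + 1`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param scale_min,scale_max Integer endpoints of the printed rating scale.
#' @param item_filter Optional integer; keep only rows for this item
#'   (the ownership item is item 3 in the seven-item questionnaire).
#'   `NULL` keeps all items.
#' @param sep Field separator (default `","`).
#' @return A data frame of rating records with columns `participant`
#'   (character), `condition` (integer 0/1), `item` (integer),
#'   `rating_raw` (integer, printed scale) and `rating_cat`
#'   (integer, 1..K).
#' @export
read_ratings <- function(path, scale_min, scale_max, item_filter = NULL,
                         sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("participant", "condition", "item", "rating")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("ratings file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ratings_from_frame(df, scale_min = scale_min, scale_max = scale_max,
                     item_filter = item_filter)
}

#' Build rating records from an in-memory data frame
#'
#' Workhorse behind [read_ratings()]; exposed so external tables can be
#' adapted without writing them to disk first.
#'
#' @inheritParams read_ratings
#' @param df Data frame with columns `participant`, `condition`, `item`,
#'   `rating`.
#' @return A rating-record data frame; see [read_ratings()].
#' @export
ratings_from_frame <- function(df, scale_min, scale_max, item_filter = NULL) {
  stopifnot(scale_max > scale_min)
  cond <- normalize_condition(df$condition)
  rating <- df$rating
  if (!is.numeric(rating)) {
    suppressWarnings(rating <- as.numeric(rating))
  }
  bad <- is.na(rating) | rating != round(rating) |
    rating < scale_min | rating > scale_max
  if (any(bad)) {
    stop("rating(s) outside the declared scale [", scale_min, ", ",
         scale_max, "] (or non-integer) in row(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  out <- data.frame(
    participant = as.character(df$participant),
    condition = cond,
    item = as.integer(df$item),
    rating_raw = as.integer(rating),
    rating_cat = as.integer(rating - scale_min + 1L),
    stringsAsFactors = FALSE
  )
  if (!is.null(item_filter)) {
    out <- out[out$item == as.integer(item_filter), , drop = FALSE]
    rownames(out) <- NULL
  }
  key <- paste(out$participant, out$condition, out$item, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    offenders <- unique(paste0("(", out$participant[dup], ", cond=",
                               out$condition[dup], ", item=", out$item[dup],
                               ")"))
    stop("duplicate (participant, condition, item) record(s): ",
         paste(offenders, collapse = "; "))
  }
  attr(out, "n_categories") <- as.integer(scale_max - scale_min + 1L)
  attr(out, "scale_min") <- as.integer(scale_min)
  out
}

# Map heterogeneous condition labels onto the internal 0/1 coding
# (0 = asynchronous, 1 = synchronous).
normalize_condition <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(lab))
  out[lab %in% c("0", "async", "asynchronous")] <- 0L
  out[lab %in% c("1", "sync", "synchronous")] <- 1L
  if (anyNA(out)) {
    stop("unrecognized condition label(s): ",
         paste(unique(lab[is.na(out)]), collapse = ", "),
         " (expected 0/1, async/sync or asynchronous/synchronous)")
  }
  out
}

#' Write rating records to CSV
#'
#' Inverse of [read_ratings()]: emits `participant,condition,item,rating`
#' with the rating on the original printed scale, UTF-8, header row and
#' `.` decimal separator, so that a write/read round trip is the identity
#' on records.
#'
#' @param records Rating-record data frame from [read_ratings()] or
#'   [ratings_from_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(records, path) {
  out <- data.frame(
    participant = records$participant,
    condition = records$condition,
    item = records$item,
    rating = records$rating_raw
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read heartbeat-tracking trials
#'
#' Reads the per-trial table of the heartbeat tracking task: for each
#' participant, up to three trials with duration in seconds, the heartbeat
#' count derived from the recording, and the count reported by the
#' participant. Expected columns: `participant`, `trial`, `duration_s`,
#' `hb_recorded`, `hb_reported`.
#'
#' Participants with a number of trials different from three are flagged
#' with a warning (their rows are still returned); a CIA score requires
#' exactly three trials. A recorded count of zero is rejected because the
#' accuracy formula divides by it.
#'
#' @param path Path to a CSV file.
#' @param sep Field separator (default `","`).
#' @return Data frame with columns `participant` (character), `trial`
#'   (integer), `duration_s` (numeric), `hb_recorded`, `hb_reported`
#'   (integers), plus an attribute `incomplete` naming participants
#'   without exactly three trials.
#' @export
read_heartbeat_trials <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("participant", "trial", "duration_s", "hb_recorded",
                "hb_reported")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("heartbeat file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  parse_int <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) | v != round(v)
    if (any(bad)) {
      stop("non-integer value in column '", col, "' at data row(s): ",
           paste(which(bad), collapse = ", "),
           " (value(s): ", paste(x[bad], collapse = ", "), ")")
    }
    as.integer(v)
  }
  out <- data.frame(
    participant = as.character(df$participant),
    trial = parse_int(df$trial, "trial"),
    duration_s = suppressWarnings(as.numeric(df$duration_s)),
    hb_recorded = parse_int(df$hb_recorded, "hb_recorded"),
    hb_reported = parse_int(df$hb_reported, "hb_reported"),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$duration_s) | out$duration_s <= 0)) {
    stop("non-positive or unparseable duration_s")
  }
  if (any(out$hb_recorded < 1L)) {
    stop("hb_recorded must be >= 1 (accuracy formula divides by it); ",
         "offending row(s): ", paste(which(out$hb_recorded < 1L),
                                     collapse = ", "))
  }
  if (any(out$hb_reported < 0L)) {
    stop("hb_reported must be non-negative")
  }
  counts <- table(out$participant)
  incomplete <- names(counts)[counts != 3L]
  if (length(incomplete) > 0L) {
    warning("participant(s) without exactly 3 trials: ",
            paste(incomplete, collapse = ", "))
  }
  attr(out, "incomplete") <- incomplete
  out
}

#' Write heartbeat-tracking trials to CSV
#'
#' @param trials Data frame as returned by [read_heartbeat_trials()] or
#'   [simulate_heartbeat_trials()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_heartbeat_trials <- function(trials, path) {
  out <- trials[, c("participant", "trial", "duration_s", "hb_recorded",
                    "hb_reported")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write precomputed CIA scores
#'
#' CSV with columns `participant,cia` (an optional `flag` column marking
#' scores outside `[0, 1]` is preserved when present).
#'
#' @param path File path.
#' @return `read_cia_scores`: data frame with columns `participant`
#'   (character) and `cia` (numeric), plus `flag` (logical) when present.
#' @export
read_cia_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant", "cia") %in% names(df))) {
    stop("CIA file must have columns 'participant' and 'cia'")
  }
  out <- data.frame(participant = as.character(df$participant),
                    cia = as.numeric(df$cia),
                    stringsAsFactors = FALSE)
  if ("flag" %in% names(df)) out$flag <- as.logical(df$flag)
  if (anyNA(out$cia)) stop("unparseable CIA value(s)")
  out
}

#' @rdname read_cia_scores
#' @param scores Data frame with columns `participant`, `cia` and
#'   optionally `flag`.
#' @export
write_cia_scores <- function(scores, path) {
  keep <- intersect(c("participant", "cia", "flag"), names(scores))
  utils::write.csv(scores[, keep], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Adapt an externally formatted ratings table
#'
#' Column-mapping adapter for open datasets whose layout differs from the
#' package's native `participant,condition,item,rating` format (for
#' instance one column per condition-item pair, or bespoke condition
#' labels). The user supplies the column names and condition labels; the
#' adapter emits standard rating records.
#'
#' @param path Path to a delimited file with a header row.
#' @param participant_col Name of the participant-identifier column.
#' @param condition_col Name of the condition column.
#' @param rating_col Name of the rating column (e.g. the ownership item).
#' @param async_label,sync_label Values of `condition_col` denoting the
#'   asynchronous and synchronous conditions.
#' @param scale_min,scale_max Printed endpoints of the rating scale
#'   (e.g. 1 and 11 for an 11-point item).
#' @param item_id Integer stamped into the `item` column of the output
#'   (default 3, the ownership item).
#' @param sep Field separator.
#' @return A rating-record data frame; see [read_ratings()].
#' @export
read_external_ratings <- function(path, participant_col, condition_col,
                                  rating_col, async_label, sync_label,
                                  scale_min, scale_max, item_id = 3L,
                                  sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(participant_col, condition_col, rating_col)) {
    if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
  }
  lab <- as.character(df[[condition_col]])
  cond <- rep(NA_integer_, length(lab))
  cond[lab == as.character(async_label)] <- 0L
  cond[lab == as.character(sync_label)] <- 1L
  if (anyNA(cond)) {
    stop("condition value(s) matching neither async_label nor sync_label: ",
         paste(unique(lab[is.na(cond)]), collapse = ", "))
  }
  ratings_from_frame(
    data.frame(participant = df[[participant_col]],
               condition = cond,
               item = as.integer(item_id),
               rating = df[[rating_col]],
               stringsAsFactors = FALSE),
    scale_min = scale_min, scale_max = scale_max
  )
}

#' Assemble the analysis dataset
#'
#' Joins rating records (one per condition) with CIA scores into the
#' listwise-complete dataset the model is fitted to. Participants lacking
#' either condition rating or a CIA score are dropped with a message;
#' participant order is deterministic (sorted by identifier) so that fits
#' are invariant to input row order.
#'
#' @param ratings Rating-record data frame (a single item; filter with
#'   `item_filter` in [read_ratings()] first if needed).
#' @param cia_scores Either a data frame with columns `participant` and
#'   `cia`, or a named numeric vector of CIA scores.
#' @param n_categories Number of ordinal categories K declared for the
#'   instrument (7 for a -3..+3 item, 11 for a 1..11 item). Declared, not
#'   inferred, so unobserved extreme categories still receive cutpoints.
#' @return An object of class `rhi_data`: list with elements
#'   `participants` (character, sorted), `cia` (named numeric),
#'   `ratings` (N x 2 integer matrix, columns `async` and `sync`,
#'   categories 1..K) and `n_categories`.
#' @export
assemble_dataset <- function(ratings, cia_scores, n_categories) {
  n_categories <- as.integer(n_categories)
  if (n_categories < 3L) stop("n_categories must be at least 3")
  items <- unique(ratings$item)
  if (length(items) > 1L) {
    stop("ratings contain multiple items (", paste(items, collapse = ", "),
         "); filter to a single item before assembling")
  }
  if (any(ratings$rating_cat < 1L | ratings$rating_cat > n_categories)) {
    stop("rating categories outside 1..K for K = ", n_categories)
  }
  if (is.data.frame(cia_scores)) {
    cia <- stats::setNames(as.numeric(cia_scores$cia),
                           as.character(cia_scores$participant))
  } else {
    if (is.null(names(cia_scores))) stop("cia_scores vector must be named")
    cia <- stats::setNames(as.numeric(cia_scores), names(cia_scores))
  }
  if (any(duplicated(names(cia)))) stop("duplicate participant in CIA scores")

  ids <- sort(unique(ratings$participant))
  has_async <- ids %in% ratings$participant[ratings$condition == 0L]
  has_sync <- ids %in% ratings$participant[ratings$condition == 1L]
  has_cia <- ids %in% names(cia) & !is.na(cia[ids])
  keep <- has_async & has_sync & has_cia
  dropped <- ids[!keep]
  if (length(dropped) > 0L) {
    reason <- ifelse(!has_cia[!keep], "no CIA score",
                     ifelse(!has_async[!keep], "missing asynchronous rating",
                            "missing synchronous rating"))
    message("dropping ", length(dropped), " incomplete participant(s): ",
            paste(paste0(dropped, " (", reason, ")"), collapse = ", "))
  }
  unused_cia <- setdiff(names(cia), ids)
  if (length(unused_cia) > 0L) {
    message("CIA score(s) without any ratings dropped: ",
            paste(unused_cia, collapse = ", "))
  }
  ids <- ids[keep]
  if (length(ids) < 2L) {
    stop("fewer than 2 complete participants; cannot assemble dataset")
  }
  rate_of <- function(cond) {
    sub <- ratings[ratings$condition == cond, ]
    stats::setNames(sub$rating_cat, sub$participant)[ids]
  }
  ratings_mat <- cbind(async = rate_of(0L), sync = rate_of(1L))
  rownames(ratings_mat) <- ids
  structure(
    list(participants = ids,
         cia = cia[ids],
         ratings = ratings_mat,
         n_categories = n_categories),
    class = "rhi_data"
  )
}

#' @export
print.rhi_data <- function(x, ...) {
  cat("<rhi_data> ", length(x$participants), " participants, K = ",
      x$n_categories, " ordinal categories\n", sep = "")
  cat("  CIA: min ", signif(min(x$cia), 3), ", median ",
      signif(stats::median(x$cia), 3), ", max ", signif(max(x$cia), 3),
      "\n", sep = "")
  tab <- function(j) paste(tabulate(x$ratings[, j], x$n_categories),
                           collapse = " ")
  cat("  rating counts (async): ", tab(1L), "\n", sep = "")
  cat("  rating counts (sync):  ", tab(2L), "\n", sep = "")
  invisible(x)
}
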