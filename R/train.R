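#' Train a Rescorla-Wagner learner on a trial stream
#'
#' Applies [rw_update()] sequentially to an ordered stream of learning
#' events and records the learner's state along the way. The outcome
#' lexicon is fixed before trial 1 (by default the union of outcomes across
#' the whole stream), so absent-outcome unlearning applies to every word
#' the learner will ever know about. Training is fully deterministic given
#' the stream.
#'
#' @param trials A tibble of learning events with list-columns `cues` and
#'   `outcomes` (character vectors per trial), e.g. from [build_schedule()],
#'   [fl_blocks()] or [read_event_stream()]. Other columns are ignored.
#' @param params An [rw_params()] object.
#' @param record_every Snapshot period in trials. A snapshot of the full
#'   association matrix is always taken at trial 0 (all zeros) and after the
#'   final trial, plus after every `record_every`-th trial in between.
#' @param known_outcomes Outcome lexicon; defaults to all outcomes occurring
#'   in `trials`. Must cover every outcome in the stream.
#'
#' @return An `rw_trajectory` object: a list with the snapshot matrices
#'   (named by trial index), the final matrix, the cue/outcome universes,
#'   the parameters and the trial count. Use [generics::tidy()] for a long
#'   (trial, cue, outcome, value) tibble, [final_state()] for the last
#'   matrix, and [autoplot.rw_trajectory()] for learning curves.
#' @examples
#' stream <- tibble::tibble(
#'   cues = rep(list("A"), 5),
#'   outcomes = rep(list("X"), 5)
#' )
#' traj <- rw_train(stream)
#' final_state(traj)["A", "X"] # 100 * (1 - 0.8^5)
#' @export
rw_train <- function(trials, params = rw_params(), record_every = 1,
                     known_outcomes = NULL) {
  stopifnot(inherits(params, "rw_params"))
  if (!is.data.frame(trials) || !all(c("cues", "outcomes") %in% names(trials))) {
    stop("`trials` must be a data frame with `cues` and `outcomes` columns",
      call. = FALSE
    )
  }
  n <- nrow(trials)
  if (n == 0) stop("empty trial stream", call. = FALSE)
  record_every <- as.integer(record_every)
  if (is.na(record_every) || record_every < 1) {
    stop("`record_every` must be a positive integer", call. = FALSE)
  }

  cue_list <- lapply(trials$cues, as.character)
  out_list <- lapply(trials$outcomes, as.character)
  all_cues <- unique(unlist(cue_list))
  stream_outcomes <- unique(unlist(out_list))
  if (is.null(known_outcomes)) {
    known_outcomes <- stream_outcomes
  } else {
    known_outcomes <- as.character(known_outcomes)
    if (!all(stream_outcomes %in% known_outcomes)) {
      stop("inconsistent lexicon: stream contains outcomes missing from ",
        "`known_outcomes`",
        call. = FALSE
      )
    }
  }
  if (length(known_outcomes) == 0) {
    stop("no outcomes anywhere in the stream", call. = FALSE)
  }

  V <- rw_matrix(all_cues, known_outcomes)
  snapshots <- vector("list", n + 1)
  keep <- c(TRUE, (seq_len(n) %% record_every == 0) | seq_len(n) == n)
  snapshots[[1]] <- V
  for (t in seq_len(n)) {
    V <- rw_update(V, cue_list[[t]], out_list[[t]],
      known_outcomes = known_outcomes, params = params
    )
    if (keep[t + 1]) snapshots[[t + 1]] <- V
  }
  idx <- which(keep) - 1L
  snapshots <- snapshots[keep]
  names(snapshots) <- idx

  structure(
    list(
      snapshots = snapshots,
      final = V,
      cues = rownames(V),
      outcomes = known_outcomes,
      params = params,
      n_trials = n,
      record_every = record_every
    ),
    class = "rw_trajectory"
  )
}

#' Final association matrix of a trajectory
#'
#' @param trajectory An `rw_trajectory` from [rw_train()].
#' @return The association matrix after the last trial.
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "rw_trajectory"))
  trajectory$final
}

#' Snapshot of a trajectory at a given trial
#'
#' @param trajectory An `rw_trajectory`.
#' @param trial Trial index; must be one of the recorded snapshots.
#' @return The association matrix after `trial` trials.
#' @export
state_at <- function(trajectory, trial) {
  stopifnot(inherits(trajectory, "rw_trajectory"))
  key <- as.character(as.integer(trial))
  if (!key %in% names(trajectory$snapshots)) {
    stop("no snapshot recorded at trial ", trial, call. = FALSE)
  }
  trajectory$snapshots[[key]]
}

#' Time-averaged association matrix over the tail of a trajectory
#'
#' When training events rotate deterministically (features cycling against
#' labels, alternating reinforcement), single-cue weights settle into a
#' stable limit cycle rather than a point; the quantity that converges is
#' the long-run time average, which approaches `lambda` times the
#' conditional probability of the outcome given the cue. This averages all
#' recorded snapshots in the last `window` trials.
#'
#' @param trajectory An `rw_trajectory`.
#' @param window Number of trailing trials to average over.
#' @return An association matrix of time-averaged values.
#' @export
tail_mean_state <- function(trajectory, window) {
  stopifnot(inherits(trajectory, "rw_trajectory"), window >= 1)
  idx <- as.integer(names(trajectory$snapshots))
  sel <- idx > trajectory$n_trials - window & idx > 0
  if (!any(sel)) stop("no snapshots inside the averaging window", call. = FALSE)
  mats <- trajectory$snapshots[sel]
  Reduce(`+`, mats) / length(mats)
}

#' @export
print.rw_trajectory <- function(x, ...) {
  cat(
    "<rw_trajectory> ", x$n_trials, " trials, ",
    length(x$cues), " cues x ", length(x$outcomes), " outcomes, ",
    length(x$snapshots), " snapshots\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a learning trajectory into a long tibble
#'
#' @param x An `rw_trajectory` from [rw_train()].
#' @param ... Unused.
#' @return A tibble with columns `trial`, `cue`, `outcome`, `value`, one row
#'   per recorded (cue, outcome) weight per snapshot.
#' @export
tidy.rw_trajectory <- function(x, ...) {
  purrr::imap_dfr(x$snapshots, function(V, trial) {
    tibble::tibble(
      trial = as.integer(trial),
      cue = rep(rownames(V), times = ncol(V)),
      outcome = rep(colnames(V), each = nrow(V)),
      value = as.vector(V)
    )
  })
}

#' One-row summary of a learning trajectory
#'
#' @param x An `rw_trajectory`.
#' @param ... Unused.
#' @return A tibble with trial/cue/outcome counts, the learner parameters,
#'   and the largest absolute weight reached.
#' @export
glance.rw_trajectory <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials,
    n_cues = length(x$cues),
    n_outcomes = length(x$outcomes),
    alpha = x$params$alpha,
    beta = x$params$beta,
    lambda = x$params$lambda,
    record_every = x$record_every,
    max_abs_value = max(abs(x$final))
  )
}
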