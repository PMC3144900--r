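#' Label activations for a stimulus
#'
#' The activation of a label given a stimulus is the sum, over the cues
#' present, of the cue-label predictive values -- exactly additive, so
#' activation is linear in the association matrix and invariant to cue
#' order. Cues the learner has never seen contribute 0.
#'
#' @param V Association matrix (cues x outcomes).
#' @param cues Character vector of cues present in the stimulus.
#' @param labels Labels to report; defaults to every outcome in `V`.
#' @return A tibble with columns `label`, `activation`.
#' @examples
#' V <- rw_matrix(c("num1", "num2"), c("one", "two"))
#' V["num2", "two"] <- 80
#' activate(V, c("num1", "num2"))
#' @export
activate <- function(V, cues, labels = colnames(V)) {
  stopifnot(is.matrix(V), is.numeric(V))
  if (any(!is.finite(V))) stop("non-finite values in association matrix", call. = FALSE)
  cues <- unique(as.character(cues))
  labels <- as.character(labels)
  present <- intersect(cues, rownames(V))
  act <- stats::setNames(numeric(length(labels)), labels)
  if (length(present) > 0) {
    known <- intersect(labels, colnames(V))
    act[known] <- colSums(V[present, known, drop = FALSE])
  }
  tibble::tibble(label = labels, activation = unname(act))
}

# Bare-metal activation sum used in per-trial choice loops.
act_sum <- function(V, cues, label) {
  if (!label %in% colnames(V)) {
    return(0)
  }
  present <- intersect(cues, rownames(V))
  if (length(present) == 0) {
    return(0)
  }
  sum(V[present, label])
}

#' Discrimination score for a set size
#'
#' How well the learned state picks out the correct number word for a
#' featureless set of `n` objects (numerosity cues only, so feature cues
#' cannot leak information). Three read-outs are available:
#' \describe{
#'   \item{`relative`}{the positive part of the correct label's activation
#'     divided by the sum of positive-part activations over all competing
#'     labels -- discrimination as competition among labels; 0 when no
#'     label is positively activated, 1 for a one-hot matrix, and invariant
#'     to scaling `V` by a positive constant.}
#'   \item{`raw`}{the single weight from the size-n numerosity cue to the
#'     correct label, the quantity plotted by raw mapping-value curves.}
#'   \item{`cue_share`}{the positive part of the size-n cue's weight to the
#'     correct label divided by the summed positive-part weights of all
#'     cues to that label: how dominant the correct set-size cue is among
#'     the label's predictors. This is the read-out under which unlearning
#'     erroneous competitor cues (background-rate error) registers as
#'     improved discrimination even when the correct cue itself is
#'     untouched, and it is used for the facilitation analysis.}
#' }
#' All are monotone read-outs of discriminability but not of each other.
#'
#' For a Label-to-Feature learner the matrix runs label -> feature; set
#' `arrangement = "LF"` to read the same scores from the transposed
#' direction (the activation a set's cues lend each label).
#'
#' @param V Association matrix.
#' @param n Set size to score; the correct label is `number_word(n)`.
#' @param labels Competing labels (must include the correct one).
#' @param metric `"relative"` (default), `"raw"` or `"cue_share"`.
#' @param arrangement `"FL"` (cues in rows, labels in columns) or `"LF"`
#'   (labels in rows, set cues in columns).
#' @return A single numeric score (in \[0, 1\] for `"relative"`).
#' @examples
#' V <- rw_matrix(paste0("num", 1:2), c("one", "two"))
#' V["num2", "two"] <- 100
#' discrimination_score(V, 2, labels = c("one", "two"))
#' @export
discrimination_score <- function(V, n, labels,
                                 metric = c("relative", "raw", "cue_share"),
                                 arrangement = c("FL", "LF")) {
  metric <- match.arg(metric)
  arrangement <- match.arg(arrangement)
  n <- as.integer(n)
  if (is.na(n) || n < 1 || n > 20) stop("`n` must lie in 1..20", call. = FALSE)
  labels <- as.character(labels)
  correct <- number_word(n)
  if (!correct %in% labels) {
    stop("the correct label `", correct, "` is not among `labels`", call. = FALSE)
  }
  if (arrangement == "LF") V <- t(V)
  cue_n <- paste0("num", n)
  if (metric == "raw") {
    if (cue_n %in% rownames(V) && correct %in% colnames(V)) {
      return(unname(V[cue_n, correct]))
    }
    return(0)
  }
  if (metric == "cue_share") {
    if (!correct %in% colnames(V)) {
      return(0)
    }
    col <- pmax(V[, correct], 0)
    num <- if (cue_n %in% rownames(V)) col[[cue_n]] else 0
    if (sum(col) <= 0) {
      return(0)
    }
    return(unname(num / sum(col)))
  }
  stim <- paste0("num", seq_len(n))
  act <- activate(V, stim, labels)
  pos <- pmax(act$activation, 0)
  denom <- sum(pos)
  if (denom <= 0) {
    return(0)
  }
  pos[act$label == correct] / denom
}

#' Discrimination curves along a trajectory
#'
#' Evaluates [discrimination_score()] at every recorded snapshot for each
#' requested set size, producing tidy learning curves.
#'
#' @param trajectory An `rw_trajectory` from [rw_train()].
#' @param sizes Set sizes to score.
#' @param labels Competing labels; defaults to every outcome (FL) or cue
#'   (LF) label in the trajectory.
#' @inheritParams discrimination_score
#' @return A tibble with columns `trial`, `set_size`, `score`.
#' @export
discrimination_curves <- function(trajectory, sizes, labels = NULL,
                                  metric = c("relative", "raw", "cue_share"),
                                  arrangement = c("FL", "LF")) {
  metric <- match.arg(metric)
  arrangement <- match.arg(arrangement)
  stopifnot(inherits(trajectory, "rw_trajectory"))
  if (is.null(labels)) {
    labels <- if (arrangement == "FL") trajectory$outcomes else trajectory$cues
  }
  purrr::imap_dfr(trajectory$snapshots, function(V, trial) {
    tibble::tibble(
      trial = as.integer(trial),
      set_size = as.integer(sizes),
      score = vapply(
        sizes,
        function(n) discrimination_score(V, n, labels, metric, arrangement),
        numeric(1)
      )
    )
  })
}

#' Trials to half-maximum discrimination
#'
#' A learnability index per set size: the number of training trials until a
#' discrimination curve first reaches half its final value. Sizes whose
#' final score is not positive never "learn" and return `NA`.
#'
#' @param curves A tibble from [discrimination_curves()].
#' @return A tibble with columns `set_size`, `final_score`,
#'   `trials_to_half_max`.
#' @export
trials_to_half_max <- function(curves) {
  stopifnot(all(c("trial", "set_size", "score") %in% names(curves)))
  curves |>
    dplyr::group_by(.data$set_size) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::summarise(
      final_score = dplyr::last(.data$score),
      trials_to_half_max = if (dplyr::last(.data$score) > 0) {
        .data$trial[which(.data$score >= dplyr::last(.data$score) / 2)[1]]
      } else {
        NA_integer_
      },
      .groups = "drop"
    )
}

#' Three-alternative forced choice from the learned state
#'
#' Mirrors the behavioural test: three candidate arrays (set sizes) are
#' shown and the learner must pick the one matching a target number word.
#' Each candidate is scored by the activation its (featureless) cue set
#' lends the target label; `"argmax"` picks the highest-scoring candidate,
#' breaking ties uniformly at random, while `"luce"` samples candidates
#' with probability proportional to the positive part of their activations
#' (uniformly if none is positive). With an all-zero matrix every choice is
#' a three-way tie, so expected accuracy is exactly 1/3 -- chance in a
#' three-choice procedure.
#'
#' @param V Association matrix (cues x labels).
#' @param target_size Set size whose number word is the target.
#' @param candidate_sizes Exactly 3 distinct candidate set sizes, one of
#'   which is `target_size`.
#' @param policy `"argmax"` or `"luce"`.
#' @return The chosen set size (single integer).
#' @examples
#' V <- rw_matrix(paste0("num", 1:6), c("two", "four", "six"))
#' withr::with_seed(1, forced_choice(V, 4, c(2, 4, 6)))
#' @export
forced_choice <- function(V, target_size, candidate_sizes,
                          policy = c("argmax", "luce")) {
  policy <- match.arg(policy)
  candidate_sizes <- as.integer(candidate_sizes)
  if (length(candidate_sizes) != 3 || anyDuplicated(candidate_sizes)) {
    stop("exactly 3 distinct candidate sizes are required", call. = FALSE)
  }
  if (!target_size %in% candidate_sizes) {
    stop("`target_size` must be one of the candidates", call. = FALSE)
  }
  target <- number_word(target_size)
  act <- vapply(
    candidate_sizes,
    function(n) act_sum(V, paste0("num", seq_len(n)), target),
    numeric(1)
  )
  if (policy == "argmax") {
    best <- which(act == max(act))
    pick <- if (length(best) == 1) best else sample(best, 1)
  } else {
    pos <- pmax(act, 0)
    prob <- if (sum(pos) > 0) pos / sum(pos) else rep(1 / 3, 3)
    pick <- sample.int(3, 1, prob = prob)
  }
  candidate_sizes[pick]
}

#' Monte-Carlo forced-choice accuracy
#'
#' Repeats [forced_choice()] over many trials with the target drawn
#' uniformly from the candidate triple, returning the proportion of correct
#' choices. Deterministic given the seed.
#'
#' @inheritParams forced_choice
#' @param n_trials Number of simulated test trials.
#' @param seed RNG seed.
#' @return Proportion correct in \[0, 1\].
#' @examples
#' V <- rw_matrix(paste0("num", 1:6), c("two", "four", "six"))
#' forced_choice_accuracy(V, c(2, 4, 6), n_trials = 1000, seed = 1)
#' @export
forced_choice_accuracy <- function(V, candidate_sizes, n_trials = 10000,
                                   policy = c("argmax", "luce"), seed = 1) {
  policy <- match.arg(policy)
  candidate_sizes <- as.integer(candidate_sizes)
  if (length(candidate_sizes) != 3 || anyDuplicated(candidate_sizes)) {
    stop("exactly 3 distinct candidate sizes are required", call. = FALSE)
  }
  # activation lent to each target word by each candidate array, fixed
  # across trials, so the per-trial draws can be done in bulk
  A <- vapply(
    number_word(candidate_sizes),
    function(target) {
      vapply(
        candidate_sizes,
        function(n) act_sum(V, paste0("num", seq_len(n)), target),
        numeric(1)
      )
    },
    numeric(3)
  )
  withr::with_seed(seed, {
    targets <- sample.int(3, n_trials, replace = TRUE)
    choice <- integer(n_trials)
    for (t in 1:3) {
      idx <- which(targets == t)
      if (length(idx) == 0) next
      if (policy == "argmax") {
        winners <- which(A[, t] == max(A[, t]))
        choice[idx] <- if (length(winners) == 1) {
          winners
        } else {
          sample(winners, length(idx), replace = TRUE)
        }
      } else {
        pos <- pmax(A[, t], 0)
        prob <- if (sum(pos) > 0) pos / sum(pos) else rep(1 / 3, 3)
        choice[idx] <- sample.int(3, length(idx), replace = TRUE, prob = prob)
      }
    }
    mean(choice == targets)
  })
}
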