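#' Build one learning event from an object set and a label
#'
#' The same physical event -- a labelled set of objects -- can be arranged
#' in two temporal orders. In Feature-to-Label (FL, postnominal) learning
#' the set's cues predict the number word, so the encoded set is the cue
#' side and the label the outcome; in Label-to-Feature (LF, prenominal)
#' learning the word is the sole cue predicting the set's features. The two
#' arrangements are exact mirrors of each other.
#'
#' The label need not match the set size (mislabelled events are
#' constructible for probing error-driven unlearning), but every headline
#' schedule labels sets correctly.
#'
#' @param set_size Number of objects, 1--20.
#' @param label Number-word outcome identifier (see [number_word()]).
#' @param arrangement `"FL"` or `"LF"`.
#' @param coding A [cue_coding()] object.
#' @param color,shape,size Feature values, required for enabled dimensions.
#' @return A list with elements `cues` and `outcomes` (character vectors).
#' @examples
#' make_trial(2, "two", "FL", cue_coding(features = FALSE))
#' make_trial(2, "two", "LF", cue_coding(features = FALSE))
#' @export
make_trial <- function(set_size, label, arrangement = c("FL", "LF"),
                       coding = cue_coding(), color = NULL, shape = NULL,
                       size = NULL) {
  arrangement <- match.arg(arrangement)
  set_cues <- encode_set(set_size,
    color = color, shape = shape, size = size,
    coding = coding
  )
  label <- as.character(label)
  if (arrangement == "FL") {
    list(cues = set_cues, outcomes = label)
  } else {
    list(cues = label, outcomes = set_cues)
  }
}

#' Build learning events for a table of labelled object sets
#'
#' Vectorised companion of [make_trial()]: takes one row per event and
#' returns the stream ready for [rw_train()].
#'
#' @param sets A data frame with columns `set_size`, `label`, and (when the
#'   coding enables features) `color`, `shape`, `size`.
#' @param arrangement `"FL"` or `"LF"`.
#' @param coding A [cue_coding()] object.
#' @return A tibble: `sets` plus `trial`, `arrangement`, and list-columns
#'   `cues` and `outcomes`.
#' @export
make_trials <- function(sets, arrangement = c("FL", "LF"),
                        coding = cue_coding()) {
  arrangement <- match.arg(arrangement)
  stopifnot(is.data.frame(sets), all(c("set_size", "label") %in% names(sets)))
  get_feat <- function(dim, i) {
    if (dim %in% names(sets)) sets[[dim]][i] else NULL
  }
  events <- lapply(seq_len(nrow(sets)), function(i) {
    make_trial(
      sets$set_size[i], sets$label[i], arrangement, coding,
      color = get_feat("color", i), shape = get_feat("shape", i),
      size = get_feat("size", i)
    )
  })
  tibble::as_tibble(sets) |>
    dplyr::mutate(
      trial = dplyr::row_number(),
      arrangement = arrangement,
      cues = lapply(events, `[[`, "cues"),
      outcomes = lapply(events, `[[`, "outcomes"),
      .before = 1
    )
}

#' Mirror a trial stream between FL and LF arrangements
#'
#' Swaps the cue and outcome sides of every event, turning a
#' Feature-to-Label stream into the Label-to-Feature stream with identical
#' event content (and vice versa).
#'
#' @param trials A tibble with list-columns `cues` and `outcomes`.
#' @return The mirrored tibble.
#' @export
mirror_trials <- function(trials) {
  stopifnot(all(c("cues", "outcomes") %in% names(trials)))
  out <- trials
  out$cues <- trials$outcomes
  out$outcomes <- trials$cues
  if ("arrangement" %in% names(out)) {
    out$arrangement <- ifelse(out$arrangement == "FL", "LF", "FL")
  }
  out
}

# Largest-remainder (Hamilton) apportionment of n items to weights.
largest_remainder <- function(weights, n) {
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative with at least one positive", call. = FALSE)
  }
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Assign rotating feature values so no single value reliably predicts any
# label: the k-th occurrence of each label walks the full color x shape x
# size grid in a fixed mixed-radix order, giving each value as even a
# co-occurrence with that label as divisibility allows.
assign_features <- function(labels, pools) {
  k <- stats::ave(seq_along(labels), labels, FUN = seq_along) - 1L
  p <- lengths(pools)
  tibble::tibble(
    color = pools$color[(k %% p[["color"]]) + 1L],
    shape = pools$shape[((k %/% p[["color"]]) %% p[["shape"]]) + 1L],
    size = pools$size[((k %/% (p[["color"]] * p[["shape"]])) %% p[["size"]]) + 1L]
  )
}

#' Build a training schedule over set sizes
#'
#' Generates an ordered stream of correctly labelled number-learning events
#' whose set-size composition follows one of three modes:
#' \describe{
#'   \item{`equal`}{each size appears `n_trials / length(sizes)` times
#'     (remainder trials, if any, go to the smallest sizes) and sizes are
#'     interleaved cyclically.}
#'   \item{`weighted-deterministic`}{per-size counts are the
#'     largest-remainder apportionment of `n_trials` to `weights`, so
#'     composition deviates from exact proportionality by less than one
#'     trial per size; trial order is a seeded shuffle.}
#'   \item{`weighted-sampled`}{sizes are drawn independently with
#'     probabilities proportional to `weights` under the seed.}
#' }
#' Feature values (when the coding enables them) rotate against labels so
#' that no single feature value is a reliable predictor of any label.
#'
#' @param sizes Integer vector of set sizes in scope.
#' @param n_trials Total number of trials.
#' @param mode Composition mode, see above.
#' @param weights Per-size relative frequencies (required for weighted
#'   modes), e.g. from [natural_weights()].
#' @param arrangement `"FL"` or `"LF"`.
#' @param coding A [cue_coding()] object.
#' @param feature_pools Named list of feature value pools, see
#'   [default_feature_pools()].
#' @param seed RNG seed; required for the weighted modes (which shuffle or
#'   sample), ignored in equal mode. The same seed reproduces the same
#'   schedule exactly.
#' @return A tibble of trials with columns `trial`, `arrangement`, `cues`,
#'   `outcomes`, `set_size`, `label` and any feature columns.
#' @examples
#' sched <- build_schedule(c(2, 4, 6), 18, mode = "equal")
#' table(sched$set_size)
#' @export
build_schedule <- function(sizes, n_trials,
                           mode = c(
                             "equal", "weighted-deterministic",
                             "weighted-sampled"
                           ),
                           weights = NULL,
                           arrangement = c("FL", "LF"),
                           coding = cue_coding(),
                           feature_pools = default_feature_pools(),
                           seed = NULL) {
  mode <- match.arg(mode)
  arrangement <- match.arg(arrangement)
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1, !anyDuplicated(sizes), n_trials >= 1)
  sizes <- sort(sizes)

  if (mode == "equal") {
    counts <- largest_remainder(rep(1, length(sizes)), n_trials)
    # interleave cyclically, smallest first, dropping exhausted sizes
    seq_sizes <- integer(0)
    left <- counts
    while (sum(left) > 0) {
      round_sizes <- sizes[left > 0]
      seq_sizes <- c(seq_sizes, round_sizes)
      left[left > 0] <- left[left > 0] - 1L
    }
  } else {
    if (is.null(weights)) stop("weighted modes need `weights`", call. = FALSE)
    if (length(weights) != length(sizes)) {
      stop("`weights` must have one entry per size", call. = FALSE)
    }
    if (any(weights < 0) || all(weights == 0)) {
      stop("weights must be non-negative with at least one positive", call. = FALSE)
    }
    if (is.null(seed)) stop("weighted modes need `seed`", call. = FALSE)
    ord <- order(sizes)
    if (mode == "weighted-deterministic") {
      counts <- largest_remainder(weights[ord], n_trials)
      seq_sizes <- withr::with_seed(
        seed,
        sample(rep(sizes[ord], times = counts))
      )
    } else {
      seq_sizes <- withr::with_seed(
        seed,
        sample(sizes[ord], n_trials, replace = TRUE, prob = weights[ord])
      )
    }
  }

  sets <- tibble::tibble(set_size = seq_sizes, label = number_word(seq_sizes))
  if (coding$features) {
    sets <- dplyr::bind_cols(sets, assign_features(sets$label, feature_pools))
  }
  make_trials(sets, arrangement, coding)
}

#' Postnominal training blocks over sets of 2, 4 and 6
#'
#' Builds the Feature-to-Label training blocks used in the facilitation
#' simulation: each block presents one item kind (a fixed feature bundle)
#' in succession from small to large -- e.g. 2 hats, 4 hats, 6 hats -- and
#' the feature bundle changes between blocks. Six blocks give the standard
#' 18-trial course (six exemplars of each set size).
#'
#' @param n_blocks Number of blocks (each contributes `length(sizes)`
#'   trials).
#' @param sizes Set sizes presented within each block, in order.
#' @param coding A [cue_coding()] object.
#' @param feature_pools Named list of feature value pools.
#' @return A trial tibble as from [build_schedule()], with a `block` column.
#' @examples
#' nrow(fl_blocks(6)) # 18
#' @export
fl_blocks <- function(n_blocks = 6, sizes = c(2, 4, 6),
                      coding = cue_coding(),
                      feature_pools = default_feature_pools()) {
  n_blocks <- as.integer(n_blocks)
  if (is.na(n_blocks) || n_blocks < 1) {
    stop("`n_blocks` must be a positive integer", call. = FALSE)
  }
  sizes <- as.integer(sizes)
  p <- lengths(feature_pools)
  b <- rep(seq_len(n_blocks), each = length(sizes)) - 1L
  sets <- tibble::tibble(
    block = b + 1L,
    set_size = rep(sizes, times = n_blocks),
    label = number_word(rep(sizes, times = n_blocks))
  )
  if (coding$features) {
    sets$color <- feature_pools$color[(b %% p[["color"]]) + 1L]
    sets$shape <- feature_pools$shape[((b %/% p[["color"]]) %% p[["shape"]]) + 1L]
    sets$size <- feature_pools$size[((b %/% (p[["color"]] * p[["shape"]])) %% p[["size"]]) + 1L]
  }
  make_trials(sets, "FL", coding)
}
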