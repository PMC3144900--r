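# Element-wise mean of association matrices, aligned on the union of
# their dimnames (missing entries read as 0).
mean_states <- function(mats) {
  cues <- unique(unlist(lapply(mats, rownames)))
  outs <- unique(unlist(lapply(mats, colnames)))
  mats <- lapply(mats, expand_rw_matrix, cues = cues, outcomes = outs)
  mats <- lapply(mats, function(m) m[cues, outs, drop = FALSE])
  Reduce(`+`, mats) / length(mats)
}

renumber_trials <- function(trials) {
  trials$trial <- seq_len(nrow(trials))
  trials
}

#' Simulation of sequencing effects in number learning
#'
#' Trains two learners on mirrored streams of the same events -- sets of
#' 2, 4 and 6 objects with competing color, shape and size cues, each size
#' equally frequent -- one Feature-to-Label (the set's cues predict the
#' number word) and one Label-to-Feature (the word predicts the set's
#' cues). Only the FL arrangement permits cue competition, so it devalues
#' the uninformative feature cues and isolates the set-size cues, while the
#' LF learner converges on plain conditional co-occurrence probabilities
#' and competing activations keep interfering at test.
#'
#' @param n_trials Total training trials (divisible by 3; 200 per size by
#'   default, ample for asymptote at the default learning rate).
#' @param params An [rw_params()] object.
#' @param record_every Snapshot period in trials.
#' @param tail_window Trailing trials over which LF weights are
#'   time-averaged for the conditional-probability read-out (rotating
#'   features put single-cue weights in a limit cycle whose mean is the
#'   converged quantity).
#' @return A `sim1_result` list with the two trajectories (`fl`, `lf`), a
#'   `scores` tibble of final discrimination scores per arrangement and
#'   size, an `fl_dominance` tibble (set-size vs best feature weight per
#'   label), an `lf_conditional` tibble comparing tail-averaged LF weights
#'   with `lambda * P(feature | label)` counted from the schedule, and the
#'   config. `tidy()` returns the scores.
#' @examples
#' \donttest{
#' sim1 <- run_sim1(n_trials = 150)
#' tidy(sim1)
#' }
#' @export
run_sim1 <- function(n_trials = 600, params = rw_params(), record_every = 1,
                     tail_window = 90) {
  coding <- cue_coding(features = TRUE)
  sizes <- c(2L, 4L, 6L)
  fl <- build_schedule(sizes, n_trials, mode = "equal", coding = coding)
  lf <- mirror_trials(fl)
  traj_fl <- rw_train(fl, params, record_every)
  traj_lf <- rw_train(lf, params, record_every)
  labels <- number_word(sizes)

  scores <- tidyr::expand_grid(
    arrangement = c("FL", "LF"),
    set_size = sizes
  ) |>
    dplyr::mutate(score = purrr::map2_dbl(
      .data$arrangement, .data$set_size,
      function(arr, n) {
        traj <- if (arr == "FL") traj_fl else traj_lf
        discrimination_score(final_state(traj), n, labels, arrangement = arr)
      }
    ))

  V_fl <- final_state(traj_fl)
  feature_cues <- grep(":", rownames(V_fl), value = TRUE)
  fl_dominance <- tibble::tibble(
    set_size = sizes,
    label = labels,
    set_size_weight = vapply(
      sizes, function(n) V_fl[paste0("num", n), number_word(n)], numeric(1)
    ),
    max_feature_weight = vapply(
      labels, function(l) max(V_fl[feature_cues, l]), numeric(1)
    )
  )

  V_lf_bar <- tail_mean_state(traj_lf, tail_window)
  n_per_label <- table(fl$label)
  cooc <- fl |>
    tidyr::pivot_longer(dplyr::any_of(c("color", "shape", "size")),
      names_to = "dimension", values_to = "value"
    ) |>
    dplyr::mutate(feature = paste0(.data$dimension, ":", .data$value)) |>
    dplyr::count(.data$label, .data$feature) |>
    dplyr::mutate(p = .data$n / as.integer(n_per_label[.data$label]))
  lf_conditional <- cooc |>
    dplyr::mutate(
      expected = params$lambda * .data$p,
      tail_mean = purrr::map2_dbl(.data$label, .data$feature, function(l, f) {
        if (l %in% rownames(V_lf_bar) && f %in% colnames(V_lf_bar)) {
          V_lf_bar[l, f]
        } else {
          0
        }
      })
    ) |>
    dplyr::select("label", "feature", "p", "expected", "tail_mean")

  structure(
    list(
      fl = traj_fl, lf = traj_lf, scores = scores,
      fl_dominance = fl_dominance, lf_conditional = lf_conditional,
      config = list(
        n_trials = n_trials, sizes = sizes, params = params,
        record_every = record_every, tail_window = tail_window
      )
    ),
    class = "sim1_result"
  )
}

#' @export
tidy.sim1_result <- function(x, ...) x$scores

#' @export
print.sim1_result <- function(x, ...) {
  cat("<sim1_result> FL vs LF over sizes", paste(x$config$sizes, collapse = ", "),
    "-", x$config$n_trials, "trials\n"
  )
  print(x$scores)
  invisible(x)
}

#' Simulation of emergent subitization limits
#'
#' Trains a Feature-to-Label learner on sets of 1--7 objects (numerosity
#' cues only, labels "one" to "seven") presented in proportion to the
#' spoken frequency of their number words, and tracks how discrimination
#' of each set size develops. Because the nested cue structure makes
#' larger sets both more confusable and rarer, small sets (1--4) are
#' discriminated quickly while 5 and 6 need markedly more training and 7
#' stays poor: a continuous learning system producing an effective
#' discontinuity. A comparison arm trains sizes 1--8 with equal frequency,
#' which removes most of the spread.
#'
#' Larger training domains (up to 20, weighted by the inverse-power
#' extrapolation of [natural_weights()]) are runnable via `sizes`, but note
#' the learner's stability bound: the summed prediction over n co-present
#' cues contracts by `|1 - n * alpha * beta|` per trial, so at the default
#' learning rate sets with 10 or more cues make training diverge.
#'
#' @param n_trials Trials per arm.
#' @param params An [rw_params()] object.
#' @param record_every Snapshot period.
#' @param seed Seed for the schedule shuffles.
#' @param features Include competing color/shape/size cues? Defaults to
#'   numerosity cues only.
#' @param sizes Set sizes in the weighted training domain.
#' @param score_sizes Set sizes whose discrimination curves are reported.
#' @return A `sim2_result` list: trajectories `weighted` and `equal`,
#'   tidy `curves` (arm, trial, set_size, score), the per-size schedule
#'   `weights`, and the config. `tidy()` returns the curves.
#' @examples
#' \donttest{
#' sim2 <- run_sim2(n_trials = 300)
#' trials_to_half_max(dplyr::filter(tidy(sim2), arm == "weighted"))
#' }
#' @export
run_sim2 <- function(n_trials = 1000, params = rw_params(), record_every = 10,
                     seed = 202, features = FALSE, sizes = 1:7,
                     score_sizes = 1:7) {
  coding <- cue_coding(features = features)
  sizes_w <- as.integer(sizes)
  weights <- natural_weights(sizes_w)
  sched_w <- build_schedule(sizes_w, n_trials,
    mode = "weighted-deterministic",
    weights = weights, coding = coding, seed = seed
  )
  traj_w <- rw_train(sched_w, params, record_every,
    known_outcomes = number_word(sizes_w)
  )
  sizes_e <- 1:8
  sched_e <- build_schedule(sizes_e, n_trials, mode = "equal", coding = coding)
  traj_e <- rw_train(sched_e, params, record_every,
    known_outcomes = number_word(sizes_e)
  )
  curves <- dplyr::bind_rows(
    weighted = discrimination_curves(
      traj_w, intersect(score_sizes, sizes_w),
      labels = number_word(sizes_w)
    ),
    equal = discrimination_curves(traj_e, score_sizes,
      labels = number_word(sizes_e)
    ),
    .id = "arm"
  )
  structure(
    list(
      weighted = traj_w, equal = traj_e, curves = curves,
      weights = tibble::tibble(set_size = sizes_w, weight = weights),
      config = list(
        n_trials = n_trials, params = params, seed = seed,
        record_every = record_every, features = features,
        score_sizes = score_sizes
      )
    ),
    class = "sim2_result"
  )
}

#' @export
tidy.sim2_result <- function(x, ...) x$curves

#' @export
print.sim2_result <- function(x, ...) {
  cat("<sim2_result>", x$config$n_trials, "trials per arm;",
    "final weighted-arm scores:\n"
  )
  fin <- x$curves |>
    dplyr::filter(.data$arm == "weighted", .data$trial == max(.data$trial))
  print(fin)
  invisible(x)
}

#' Simulation of facilitation of untrained numbers
#'
#' Both arms share 110 trials of Feature-to-Label pretraining on the
#' natural (spoken-frequency) distribution of sets 1--7 with competing
#' shape and size cues. The treatment arm then receives six postnominal training
#' blocks of 2, 4 and 6 objects (18 trials, [fl_blocks()]); the baseline
#' arm instead continues for 18 further natural-distribution trials,
#' replicated with five distinct seeds whose learned states are averaged
#' (18 trials cannot deterministically honour the frequency distribution,
#' so they are sampled). Improvement is the change in discrimination score
#' between trial 110 and trial 128.
#'
#' The default read-out is the `cue_share` metric of
#' [discrimination_score()]: the share of the correct set-size cue among
#' all positive predictors of its number word. This is the quantity the
#' facilitation mechanism operates on -- block training on 2, 4 and 6
#' generates prediction error that unlearns the erroneous competitor cues
#' to "five" and "seven" (smaller numerosity cues and object features),
#' so the correct cues gain predictive share without ever being reinforced
#' themselves. Trained sizes, by contrast, gain little: on a 4-trial every
#' cue present is reinforced as a predictor of "four" alike.
#'
#' @param n_pretrain Pretraining trials shared by both arms.
#' @param n_blocks Number of FL blocks in the treatment arm (3 trials
#'   each).
#' @param n_baseline_reps Baseline replicates to average.
#' @param params An [rw_params()] object.
#' @param seed Master seed: the pretraining shuffle uses `seed`, baseline
#'   replicate i uses `seed + i`.
#' @param score_sizes Set sizes scored for the improvement table.
#' @param metric Discrimination read-out for the improvement table; see
#'   [discrimination_score()] and Details.
#' @return A `sim3_result` list: the `treatment` trajectory, the list of
#'   `baseline` trajectories, an `improvement` tibble (arm, set_size,
#'   score_110, score_128, improvement; baseline from the averaged state),
#'   a `baseline_reps` tibble of per-replicate improvements, and the
#'   config. `tidy()` returns the improvement table.
#' @examples
#' \donttest{
#' sim3 <- run_sim3()
#' tidy(sim3)
#' }
#' @export
run_sim3 <- function(n_pretrain = 110, n_blocks = 6, n_baseline_reps = 5,
                     params = rw_params(), seed = 303, score_sizes = 1:7,
                     metric = c("cue_share", "relative", "raw")) {
  metric <- match.arg(metric)
  coding <- cue_coding(features = TRUE, dimensions = c("shape", "size"))
  sizes <- 1:7
  weights <- natural_weights(sizes)
  lexicon <- number_word(sizes)
  pretrain <- build_schedule(sizes, n_pretrain,
    mode = "weighted-deterministic",
    weights = weights, coding = coding, seed = seed
  )
  n_extra <- n_blocks * 3
  treatment_stream <- renumber_trials(
    dplyr::bind_rows(pretrain, fl_blocks(n_blocks, coding = coding))
  )
  traj_t <- rw_train(treatment_stream, params,
    record_every = 1,
    known_outcomes = lexicon
  )
  baselines <- lapply(seq_len(n_baseline_reps), function(i) {
    extra <- build_schedule(sizes, n_extra,
      mode = "weighted-sampled",
      weights = weights, coding = coding, seed = seed + i
    )
    rw_train(renumber_trials(dplyr::bind_rows(pretrain, extra)), params,
      record_every = 1, known_outcomes = lexicon
    )
  })
  n_total <- n_pretrain + n_extra

  score_all <- function(V) {
    vapply(
      score_sizes,
      function(n) discrimination_score(V, n, lexicon, metric = metric),
      numeric(1)
    )
  }
  s110 <- score_all(state_at(traj_t, n_pretrain))
  s_treat <- score_all(state_at(traj_t, n_total))
  V_base <- mean_states(lapply(baselines, state_at, trial = n_total))
  s_base <- score_all(V_base)

  improvement <- dplyr::bind_rows(
    tibble::tibble(
      arm = "treatment", set_size = score_sizes,
      score_110 = s110, score_128 = s_treat
    ),
    tibble::tibble(
      arm = "baseline", set_size = score_sizes,
      score_110 = s110, score_128 = s_base
    )
  ) |>
    dplyr::mutate(improvement = .data$score_128 - .data$score_110)

  baseline_reps <- purrr::imap_dfr(baselines, function(traj, i) {
    s <- score_all(state_at(traj, n_total))
    tibble::tibble(
      rep = i, set_size = score_sizes,
      score_128 = s, improvement = s - s110
    )
  })

  structure(
    list(
      treatment = traj_t, baseline = baselines,
      improvement = improvement, baseline_reps = baseline_reps,
      config = list(
        n_pretrain = n_pretrain, n_blocks = n_blocks,
        n_baseline_reps = n_baseline_reps, params = params, seed = seed,
        score_sizes = score_sizes, n_total = n_total, metric = metric
      )
    ),
    class = "sim3_result"
  )
}

#' @export
tidy.sim3_result <- function(x, ...) x$improvement

#' @export
print.sim3_result <- function(x, ...) {
  cat("<sim3_result>", x$config$n_pretrain, "+",
    x$config$n_blocks * 3, "trials; improvement by arm:\n"
  )
  print(x$improvement)
  invisible(x)
}
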