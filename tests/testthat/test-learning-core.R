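test_that("single-trial updates follow the discrepancy rule", {
  p <- rw_params()

  # acquisition from zero
  V <- rw_matrix("A", "X")
  V <- rw_update(V, "A", "X", params = p)
  expect_equal(V["A", "X"], 20)

  # at asymptote the delta vanishes
  V <- rw_matrix("A", "X")
  V["A", "X"] <- 100
  expect_equal(rw_update(V, "A", "X", params = p)["A", "X"], 100)

  # overexpectation: compound predicting 120 is driven down
  V <- rw_matrix(c("A", "B"), "X")
  V["A", "X"] <- 60
  V["B", "X"] <- 60
  V2 <- rw_update(V, c("A", "B"), "X", params = p)
  expect_equal(unname(V2[, "X"]), c(56, 56))

  # error-driven unlearning of an absent outcome
  V <- rw_matrix("A", c("X", "Y"))
  V["A", "Y"] <- 50
  V2 <- rw_update(V, "A", "X", known_outcomes = c("X", "Y"), params = p)
  expect_equal(V2["A", "Y"], 40)
  expect_equal(V2["A", "X"], 20)
})

test_that("updates are simultaneous and absent cues untouched", {
  V <- rw_matrix(c("A", "B", "C"), "X")
  V["A", "X"] <- 30
  V["B", "X"] <- 40
  V["C", "X"] <- 5
  V2 <- rw_update(V, c("A", "B"), "X")
  # both present cues get the same delta, computed from the pre-update sum
  delta <- 0.2 * (100 - 70)
  expect_equal(V2["A", "X"], 30 + delta)
  expect_equal(V2["B", "X"], 40 + delta)
  expect_equal(V2["C", "X"], 5)
})

test_that("invalid trials are rejected", {
  V <- rw_matrix("A", "X")
  expect_error(rw_update(V, "A", "Z"), "lexicon")
  expect_error(rw_update(V, character(0), "X"), "at least one cue")
  V["A", "X"] <- NaN
  expect_error(rw_update(V, "A", "X"), "non-finite")
  expect_error(rw_matrix(c("A", "X"), "X"), "overlap")
  expect_error(rw_params(beta = 1.5), "beta")
  expect_error(rw_params(lambda = 0), "lambda")
})

test_that("training matches the independent brute-force learner", {
  set.seed(42)
  cues_pool <- c("A", "B", "C", "D")
  outs_pool <- c("X", "Y")
  trial_list <- lapply(1:40, function(i) {
    list(
      cues = sample(cues_pool, sample(1:3, 1)),
      outcomes = if (runif(1) < 0.2) character(0) else sample(outs_pool, 1)
    )
  })
  trials <- tibble::tibble(
    cues = lapply(trial_list, `[[`, "cues"),
    outcomes = lapply(trial_list, `[[`, "outcomes")
  )
  traj <- rw_train(trials, known_outcomes = outs_pool)
  oracle <- naive_rw_train(trial_list, outs_pool)
  V <- final_state(traj)
  for (key in names(oracle)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    expect_equal(V[parts[1], parts[2]], oracle[[key]], tolerance = 1e-12)
  }
})

test_that("single cue acquisition matches the closed form exactly", {
  traj <- rw_train(constant_stream("A", "X", 50), record_every = 1)
  got <- vapply(0:50, function(t) state_at(traj, t)["A", "X"], numeric(1))
  expect_equal(got, 100 * (1 - 0.8^(0:50)), tolerance = 1e-9)
  expect_equal(final_state(rw_train(constant_stream("A", "X", 5)))["A", "X"],
    67.232,
    tolerance = 1e-9
  )
})

test_that("learning is negatively accelerated and asymptotic", {
  traj <- rw_train(constant_stream(c("A", "B"), "X", 200), record_every = 1)
  v <- vapply(
    0:200,
    function(t) sum(state_at(traj, t)[, "X"]), numeric(1)
  )
  steps <- abs(diff(v))
  expect_true(all(diff(steps) <= 1e-9))
  expect_lt(abs(v[201] - 100), 1e-6)
  # column sums over co-present cues never exceed lambda materially
  expect_true(all(v <= 100 + 1e-9))
})

test_that("pretraining a competitor blocks the redundant cue", {
  pre <- constant_stream("A", "X", 50)
  compound <- constant_stream(c("A", "B"), "X", 50)
  blocked <- final_state(rw_train(dplyr::bind_rows(pre, compound)))["B", "X"]
  control <- final_state(rw_train(compound))["B", "X"]
  expect_lt(blocked, 1)
  expect_lt(blocked, control)
  expect_gt(control, 40) # without pretraining B shares the asymptote
})

test_that("an outcome-free trial extinguishes prediction toward zero", {
  V <- rw_matrix(c("A", "B"), c("X", "Y"))
  V["A", "X"] <- 70
  V["B", "X"] <- 10
  V2 <- rw_update(V, c("A", "B"), character(0), known_outcomes = c("X", "Y"))
  # positively predicted outcomes are unlearned, never strengthened
  expect_true(all(V2 <= V + 1e-12))
  # a net-negative prediction is corrected upward: the discrepancy is
  # 0 - (sum V), so extinction always moves total prediction toward zero
  V["B", "Y"] <- -10
  V3 <- rw_update(V, c("A", "B"), character(0), known_outcomes = c("X", "Y"))
  expect_lt(abs(sum(V3[, "Y"])), abs(sum(V[, "Y"])))
  expect_lt(abs(sum(V3[, "X"])), abs(sum(V[, "X"])))
})

test_that("trajectories record snapshots as promised", {
  traj <- rw_train(constant_stream("A", "X", 25), record_every = 10)
  idx <- as.integer(names(traj$snapshots))
  expect_true(all(diff(idx) > 0))
  expect_equal(idx[1], 0)
  expect_equal(idx[length(idx)], 25)
  expect_true(all(state_at(traj, 0) == 0))
  expect_error(state_at(traj, 13), "no snapshot")
  expect_error(rw_train(tibble::tibble(cues = list(), outcomes = list())), "empty")
  # deterministic given the stream
  traj2 <- rw_train(constant_stream("A", "X", 25), record_every = 10)
  expect_identical(final_state(traj), final_state(traj2))
})

test_that("label-only cue converges to lambda times co-occurrence probability", {
  # feature present on exactly half of the label's trials, alternating
  alt <- tibble::tibble(
    cues = rep(list("L"), 400),
    outcomes = rep(list("f", character(0)), 200)
  )
  traj <- rw_train(alt, known_outcomes = "f")
  expect_equal(tail_mean_state(traj, 50)["L", "f"], 50, tolerance = 1)
})

test_that("tidy and glance summarise a trajectory", {
  traj <- rw_train(constant_stream(c("A", "B"), "X", 10), record_every = 5)
  td <- tidy(traj)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("trial", "cue", "outcome", "value"))
  expect_equal(nrow(td), 3 * 2) # snapshots at 0, 5, 10 x 2 cues x 1 outcome
  gl <- glance(traj)
  expect_equal(gl$n_trials, 10)
  expect_equal(gl$beta, 0.2)
})
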