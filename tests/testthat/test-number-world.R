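test_that("encode_set produces nested numerosity cues plus features", {
  bare <- cue_coding(features = FALSE)
  expect_equal(encode_set(1, coding = bare), "num1")
  expect_setequal(
    encode_set(3, color = "red", shape = "round", size = "small"),
    c("num1", "num2", "num3", "color:red", "shape:round", "size:small")
  )
  expect_error(encode_set(0, coding = bare), "1..20")
  expect_error(encode_set(21, coding = bare), "1..20")
  expect_error(encode_set(3, coding = cue_coding()), "color")
})

test_that("numerosity cues nest strictly and count the set", {
  bare <- cue_coding(features = FALSE)
  for (n in 1:19) {
    lo <- encode_set(n, coding = bare)
    hi <- encode_set(n + 1, coding = bare)
    expect_length(lo, n)
    expect_true(all(lo %in% hi))
    expect_gt(length(setdiff(hi, lo)), 0)
  }
})

test_that("FL and LF trials are exact mirrors of the same event", {
  bare <- cue_coding(features = FALSE)
  fl <- make_trial(2, "two", "FL", bare)
  lf <- make_trial(2, "two", "LF", bare)
  expect_setequal(fl$cues, c("num1", "num2"))
  expect_equal(fl$outcomes, "two")
  expect_equal(lf$cues, fl$outcomes)
  expect_setequal(lf$outcomes, fl$cues)
  expect_error(make_trial(2, "two", "XY", bare))
  # mislabelled events are constructible for unlearning probes
  odd <- make_trial(3, "five", "FL", bare)
  expect_equal(odd$outcomes, "five")

  sched <- build_schedule(c(2, 4), 8, mode = "equal", coding = bare)
  mirrored <- mirror_trials(sched)
  expect_equal(mirrored$cues, sched$outcomes)
  expect_equal(mirror_trials(mirrored)$cues, sched$cues)
  expect_equal(unique(mirrored$arrangement), "LF")
})

test_that("equal schedules balance and interleave sizes", {
  sched <- build_schedule(c(2, 4, 6), 18, mode = "equal")
  expect_equal(nrow(sched), 18)
  expect_equal(unname(table(sched$set_size)), rep(6L, 3), ignore_attr = TRUE)
  expect_equal(sched$set_size[1:6], c(2, 4, 6, 2, 4, 6))
  expect_equal(sched$label, number_word(sched$set_size))
})

test_that("weighted-deterministic schedules follow largest-remainder counts", {
  w <- natural_weights(1:7)
  sched <- build_schedule(1:7, 110,
    mode = "weighted-deterministic",
    weights = w, coding = cue_coding(features = FALSE), seed = 5
  )
  counts <- table(factor(sched$set_size, levels = 1:7))
  expect_equal(unname(counts[["1"]]), 36) # 110 * 856/2602 = 36.19 -> 36
  expect_equal(sum(counts), 110)
  # composition within one trial of exact proportionality
  expect_true(all(abs(as.integer(counts) - 110 * w / sum(w)) < 1))
  # same seed, same order; different seed, same counts
  sched2 <- build_schedule(1:7, 110,
    mode = "weighted-deterministic",
    weights = w, coding = cue_coding(features = FALSE), seed = 5
  )
  expect_identical(sched$set_size, sched2$set_size)
  sched3 <- build_schedule(1:7, 110,
    mode = "weighted-deterministic",
    weights = w, coding = cue_coding(features = FALSE), seed = 6
  )
  expect_equal(table(sched3$set_size), table(sched$set_size))
})

test_that("weighted-sampled schedules are reproducible under the seed", {
  w <- c(3, 2, 1)
  a <- build_schedule(c(1, 2, 3), 30,
    mode = "weighted-sampled", weights = w,
    coding = cue_coding(features = FALSE), seed = 9
  )
  b <- build_schedule(c(1, 2, 3), 30,
    mode = "weighted-sampled", weights = w,
    coding = cue_coding(features = FALSE), seed = 9
  )
  expect_identical(a$set_size, b$set_size)
  expect_error(
    build_schedule(1:3, 10, mode = "weighted-sampled", weights = c(0, 0, 0), seed = 1),
    "weights"
  )
  expect_error(
    build_schedule(1:3, 10, mode = "weighted-sampled", weights = w),
    "seed"
  )
})

test_that("no feature value reliably predicts any label", {
  sched <- build_schedule(c(2, 4, 6), 90, mode = "equal")
  long <- tidyr::pivot_longer(sched, c("color", "shape", "size"),
    names_to = "dim", values_to = "value"
  )
  cond <- long |>
    dplyr::count(label, dim, value) |>
    dplyr::group_by(label, dim) |>
    dplyr::mutate(p = n / sum(n))
  expect_true(all(cond$p <= 0.5))
  # and every feature value co-occurs with every label
  combos <- long |> dplyr::distinct(label, value)
  expect_equal(nrow(combos), 3 * 9)
})

test_that("postnominal blocks present one item from small to large", {
  blocks <- fl_blocks(6)
  expect_equal(nrow(blocks), 18)
  expect_equal(blocks$set_size, rep(c(2, 4, 6), 6))
  expect_equal(unique(blocks$arrangement), "FL")
  per_block <- split(blocks[c("color", "shape", "size")], blocks$block)
  for (b in per_block) expect_equal(nrow(dplyr::distinct(b)), 1)
  # items differ between consecutive blocks
  bundles <- vapply(
    per_block,
    function(b) paste(b$color[1], b$shape[1], b$size[1]), character(1)
  )
  expect_equal(length(unique(bundles)), 6)
  expect_equal(nrow(fl_blocks(1)), 3)
  expect_error(fl_blocks(0), "positive")
})
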