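test_that("activation is the additive read-out of present cues", {
  V <- rw_matrix(c("num1", "num2", "color:red"), c("one", "two"))
  V["num2", "two"] <- 80
  V["color:red", "two"] <- 5
  act <- activate(V, c("num1", "num2", "color:red"))
  expect_equal(act$activation[act$label == "two"], 85)
  expect_equal(act$activation[act$label == "one"], 0)
  # permutation invariance and unknown-cue neutrality
  act2 <- activate(V, c("color:red", "never-seen", "num2", "num1"))
  expect_equal(act2$activation, act$activation)
  # zero matrix activates nothing
  expect_equal(activate(rw_matrix("a", "x"), "a")$activation, 0)
})

test_that("activation is linear in the association matrix", {
  set.seed(7)
  cues <- paste0("c", 1:4)
  outs <- paste0("o", 1:3)
  V1 <- matrix(rnorm(12), 4, 3, dimnames = list(cues, outs))
  V2 <- matrix(rnorm(12), 4, 3, dimnames = list(cues, outs))
  probe <- c("c1", "c3")
  expect_equal(
    activate(V1 + V2, probe)$activation,
    activate(V1, probe)$activation + activate(V2, probe)$activation
  )
})

test_that("discrimination scores cover their defining cases", {
  labels <- number_word(1:3)
  # the discriminative equilibrium matrix (correct cue positive, next-size
  # cue inhibitory) picks out every size perfectly
  eq <- rw_matrix(paste0("num", 1:4), labels)
  for (n in 1:3) {
    eq[paste0("num", n), number_word(n)] <- 100
    eq[paste0("num", n + 1), number_word(n)] <- -100
  }
  for (n in 1:3) {
    expect_equal(discrimination_score(eq, n, labels), 1)
  }
  # a plain one-hot matrix cannot: nested stimuli activate all smaller
  # numbers' labels too, so scores fall as 1, 1/2, 1/3
  onehot <- rw_matrix(paste0("num", 1:3), labels)
  for (n in 1:3) onehot[paste0("num", n), number_word(n)] <- 100
  expect_equal(
    vapply(1:3, function(n) discrimination_score(onehot, n, labels), numeric(1)),
    c(1, 1 / 2, 1 / 3)
  )
  zero <- rw_matrix(paste0("num", 1:3), labels)
  expect_equal(discrimination_score(zero, 2, labels), 0)
  uniform <- zero
  uniform[1, ] <- 10 # num1 activates all three labels equally
  expect_equal(discrimination_score(uniform, 1, labels), 1 / 3)
  # positive scale invariance of the relative score
  V <- onehot
  V["num1", "two"] <- 30
  expect_equal(
    discrimination_score(V, 2, labels),
    discrimination_score(V * 17, 2, labels)
  )
  # raw variant is the single mapping weight
  expect_equal(discrimination_score(V, 2, labels, metric = "raw"), 100)
  expect_error(discrimination_score(V, 25, labels), "1..20")
  expect_error(discrimination_score(V, 3, c("one", "two")), "not among")
})

test_that("cue-share scores track predictor dominance within a label", {
  labels <- number_word(1:3)
  V <- rw_matrix(c(paste0("num", 1:3), "shape:round"), labels)
  V["num2", "two"] <- 60
  V["shape:round", "two"] <- 20
  V["num1", "two"] <- 20
  expect_equal(discrimination_score(V, 2, labels, metric = "cue_share"), 0.6)
  # unlearning a competitor raises the share without touching num2
  V["shape:round", "two"] <- -5
  expect_equal(discrimination_score(V, 2, labels, metric = "cue_share"), 0.75)
  expect_equal(discrimination_score(V, 3, labels, metric = "cue_share"), 0)
})

test_that("LF arrangement scores read the transposed direction", {
  labels <- number_word(1:2)
  V <- rw_matrix(labels, paste0("num", 1:2)) # label -> feature matrix
  V["two", "num1"] <- 50
  V["two", "num2"] <- 50
  V["one", "num1"] <- 50
  s2 <- discrimination_score(V, 2, labels, arrangement = "LF")
  # stimulus {num1, num2}: act(two) = 100, act(one) = 50
  expect_equal(s2, 100 / 150)
})

test_that("trials to half-maximum scans curves as defined", {
  curves <- tibble::tibble(
    trial = rep(c(0, 10, 20, 30), 2),
    set_size = rep(1:2, each = 4),
    score = c(0, 0.6, 0.8, 1, 0, 0, 0, 0)
  )
  hm <- trials_to_half_max(curves)
  expect_equal(hm$trials_to_half_max[hm$set_size == 1], 10)
  expect_true(is.na(hm$trials_to_half_max[hm$set_size == 2]))
  expect_equal(hm$final_score, c(1, 0))
})

test_that("forced choice follows activations and breaks ties at chance", {
  labels <- number_word(c(2, 4, 6))
  # discriminative equilibrium matrix: correct cue positive, next size
  # inhibitory, so each array activates exactly its own word
  V <- rw_matrix(paste0("num", 1:7), labels)
  for (n in c(2, 4, 6)) {
    V[paste0("num", n), number_word(n)] <- 100
    V[paste0("num", n + 1), number_word(n)] <- -100
  }
  expect_equal(forced_choice_accuracy(V, c(2, 4, 6), 500, seed = 1), 1)
  for (target in c(2, 4, 6)) {
    expect_equal(forced_choice(V, target, c(2, 4, 6)), target)
  }
  # a plain one-hot matrix ties upward through the nesting: a 4-array
  # contains num2, so "two" cannot be told apart below the largest array
  onehot <- rw_matrix(paste0("num", 1:6), labels)
  for (n in c(2, 4, 6)) onehot[paste0("num", n), number_word(n)] <- 100
  acc <- forced_choice_accuracy(onehot, c(2, 4, 6), 20000, seed = 2)
  expect_equal(acc, (1 / 3 + 1 / 2 + 1) / 3, tolerance = 0.02)
  expect_error(forced_choice(V, 2, c(2, 2, 4)), "distinct")
  expect_error(forced_choice(V, 3, c(2, 4, 6)), "candidates")
})

test_that("the Luce rule samples by positive share, scale-free", {
  labels <- number_word(c(1, 2, 3))
  V <- rw_matrix(paste0("num", 1:3), labels)
  # target "one": arrays 1, 2, 3 all contain num1; give activations 2, 1, 1
  V["num1", "one"] <- 2
  V["num2", "one"] <- -1
  # array1: 2, array2: 2-1 = 1, array3: 2-1+0 = 1
  draws <- withr::with_seed(99, replicate(6000, {
    forced_choice(V, 1, c(1, 2, 3), policy = "luce")
  }))
  freq <- table(factor(draws, levels = 1:3)) / 6000
  expect_equal(unname(as.vector(freq)), c(0.5, 0.25, 0.25), tolerance = 0.03)
  # scaling all values leaves the choice distribution unchanged
  draws2 <- withr::with_seed(99, replicate(200, {
    forced_choice(V * 40, 1, c(1, 2, 3), policy = "luce")
  }))
  draws1 <- withr::with_seed(99, replicate(200, {
    forced_choice(V, 1, c(1, 2, 3), policy = "luce")
  }))
  expect_identical(draws1, draws2)
})
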