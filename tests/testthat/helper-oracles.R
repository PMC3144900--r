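# Independent brute-force Rescorla-Wagner oracle: plain nested loops over a
# named list-of-lists state, no matrix algebra shared with the package.
naive_rw_update <- function(state, cues, outcomes, known_outcomes,
                            alpha = 1, beta = 0.2, lambda = 100) {
  totals <- list()
  for (o in known_outcomes) {
    tot <- 0
    for (c in cues) {
      key <- paste(c, o, sep = "|")
      if (!is.null(state[[key]])) tot <- tot + state[[key]]
    }
    totals[[o]] <- tot
  }
  for (o in known_outcomes) {
    lam <- if (o %in% outcomes) lambda else 0
    delta <- alpha * beta * (lam - totals[[o]])
    for (c in cues) {
      key <- paste(c, o, sep = "|")
      prev <- if (is.null(state[[key]])) 0 else state[[key]]
      state[[key]] <- prev + delta
    }
  }
  state
}

naive_rw_train <- function(trial_list, known_outcomes,
                           alpha = 1, beta = 0.2, lambda = 100) {
  state <- list()
  for (tr in trial_list) {
    state <- naive_rw_update(
      state, tr$cues, tr$outcomes, known_outcomes,
      alpha, beta, lambda
    )
  }
  state
}

# A constant-reinforcement stream cues -> outcome, as a trials tibble.
constant_stream <- function(cues, outcome, n) {
  tibble::tibble(
    cues = rep(list(cues), n),
    outcomes = rep(list(outcome), n)
  )
}
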