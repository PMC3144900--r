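#' Create an empty association matrix
#'
#' The learner's entire state is a matrix of predictive values V indexed by
#' (cue, outcome). Absent pairs read as exactly 0, so a fresh matrix is all
#' zeros. Values share the units of `lambda` (0--100 by default) and may go
#' negative: net inhibitory associations are permitted and the unlearning
#' account depends on downward movement, so no clipping is applied anywhere.
#'
#' @param cues Character vector of cue identifiers (rows).
#' @param outcomes Character vector of outcome identifiers (columns). Cue and
#'   outcome namespaces must be disjoint.
#' @return A numeric matrix with `cues` as rownames and `outcomes` as
#'   colnames, initialised to zero.
#' @examples
#' rw_matrix(c("num1", "num2"), c("one", "two"))
#' @export
rw_matrix <- function(cues, outcomes) {
  cues <- as.character(cues)
  outcomes <- as.character(outcomes)
  if (anyDuplicated(cues)) stop("duplicate cue identifiers", call. = FALSE)
  if (anyDuplicated(outcomes)) stop("duplicate outcome identifiers", call. = FALSE)
  clash <- intersect(cues, outcomes)
  if (length(clash) > 0) {
    stop(
      "cue and outcome namespaces overlap: ",
      paste(clash, collapse = ", "),
      call. = FALSE
    )
  }
  matrix(
    0,
    nrow = length(cues), ncol = length(outcomes),
    dimnames = list(cues, outcomes)
  )
}

# Grow V with zero rows/columns so it covers the given cues and outcomes.
expand_rw_matrix <- function(V, cues, outcomes) {
  new_cues <- setdiff(cues, rownames(V))
  new_outs <- setdiff(outcomes, colnames(V))
  if (length(new_cues) > 0) {
    V <- rbind(V, matrix(
      0,
      nrow = length(new_cues), ncol = ncol(V),
      dimnames = list(new_cues, colnames(V))
    ))
  }
  if (length(new_outs) > 0) {
    V <- cbind(V, matrix(
      0,
      nrow = nrow(V), ncol = length(new_outs),
      dimnames = list(rownames(V), new_outs)
    ))
  }
  V
}

#' Apply one Rescorla-Wagner learning trial
#'
#' Updates the association matrix for a single discrete learning event. For
#' every cue `c` present on the trial and every outcome `o` in the learner's
#' fixed lexicon (`known_outcomes`), the change in predictive value is the
#' discrepancy rule
#' \deqn{\Delta V(c, o) = \alpha \beta (\lambda_o - \sum_j V(c_j, o))}
#' where the sum runs over the cues present on the trial and
#' `lambda_o = params$lambda` if `o` occurred on the trial and 0 otherwise
#' (an expected outcome that fails to occur supports no associative
#' strength, so its cues are driven downward). All deltas are computed from
#' the pre-update state, so the within-trial update is simultaneous and
#' order-free. Weights of absent cues are untouched.
#'
#' @param V Association matrix from [rw_matrix()] or a previous update; rows
#'   and columns are grown automatically for unseen cues and for outcomes in
#'   `known_outcomes`.
#' @param cues Character vector of cues present on the trial (non-empty).
#' @param outcomes Character vector of outcomes present on the trial; may be
#'   empty (a pure extinction trial, which can only decrease or preserve the
#'   touched weights).
#' @param known_outcomes The learner's full outcome lexicon, fixed before
#'   training starts. Every outcome on the trial must be in it; all of its
#'   members receive an update (outcomes at zero prediction get a zero delta,
#'   so this is safe and matches the requirement that every erroneously
#'   predictable word is unlearned).
#' @param params An [rw_params()] object.
#' @return The updated association matrix.
#' @examples
#' V <- rw_matrix("A", "X")
#' rw_update(V, cues = "A", outcomes = "X") # 0.2 * (100 - 0) = 20
#' @export
rw_update <- function(V, cues, outcomes,
                      known_outcomes = colnames(V),
                      params = rw_params()) {
  stopifnot(is.matrix(V), is.numeric(V), inherits(params, "rw_params"))
  cues <- as.character(cues)
  outcomes <- as.character(outcomes)
  known_outcomes <- as.character(known_outcomes)
  if (length(cues) == 0) stop("a trial must have at least one cue", call. = FALSE)
  if (anyDuplicated(cues)) cues <- unique(cues)
  if (!all(outcomes %in% known_outcomes)) {
    stop(
      "inconsistent lexicon: trial outcome(s) not in `known_outcomes`: ",
      paste(setdiff(outcomes, known_outcomes), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(intersect(cues, known_outcomes)) > 0) {
    stop("cue and outcome namespaces overlap", call. = FALSE)
  }
  if (any(!is.finite(V))) stop("non-finite values in association matrix", call. = FALSE)

  V <- expand_rw_matrix(V, cues, known_outcomes)
  rate <- params$alpha * params$beta
  lam <- ifelse(known_outcomes %in% outcomes, params$lambda, 0)
  total <- colSums(V[cues, known_outcomes, drop = FALSE])
  delta <- rate * (lam - total) # one delta per outcome, shared by present cues
  V[cues, known_outcomes] <- V[cues, known_outcomes, drop = FALSE] +
    rep(delta, each = length(cues))
  V
}
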