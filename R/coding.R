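#' English number-word labels
#'
#' Maps set sizes 1--20 to their English number words, used as outcome
#' identifiers throughout the simulations.
#'
#' @param n Integer vector of set sizes in 1--20.
#' @return Character vector of number words ("one", "two", ...).
#' @examples
#' number_word(c(1, 7, 20))
#' @export
number_word <- function(n) {
  words <- c(
    "one", "two", "three", "four", "five", "six", "seven", "eight",
    "nine", "ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
    "sixteen", "seventeen", "eighteen", "nineteen", "twenty"
  )
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 1) || any(n > 20)) {
    stop("set sizes must be integers in 1..20", call. = FALSE)
  }
  words[n]
}

#' Default feature pools
#'
#' Three values on each of three competing feature dimensions (color, shape,
#' size). Pool sizes are a modelling choice: three values per dimension give
#' every feature a non-trivial but unreliable co-occurrence with every
#' label when rotated across a schedule.
#'
#' @return A named list of character vectors (`color`, `shape`, `size`).
#' @export
default_feature_pools <- function() {
  list(
    color = c("red", "green", "blue"),
    shape = c("round", "square", "star"),
    size = c("small", "medium", "large")
  )
}

#' Cue coding for object sets
#'
#' Declares how a set of objects is translated into discrete cues. The
#' numerosity scheme is nested: a set of n objects activates the numerosity
#' cues `num1 .. numN`, so the cue to set-size one is present in every set,
#' the cue to two in every set greater than one, and so on. This containment
#' structure is what makes larger sets progressively more confusable and is
#' the source of the graded difficulty of number discrimination. Optionally,
#' one cue per feature dimension (color/shape/size) is added as a competitor.
#'
#' @param features Logical: include the color/shape/size feature cues?
#' @param dimensions Which feature dimensions to include when `features` is
#'   `TRUE`.
#' @return An object of class `cue_coding`.
#' @examples
#' cue_coding()
#' cue_coding(features = FALSE)
#' @export
cue_coding <- function(features = TRUE,
                       dimensions = c("color", "shape", "size")) {
  dimensions <- match.arg(dimensions, several.ok = TRUE)
  structure(
    list(features = isTRUE(features), dimensions = dimensions),
    class = "cue_coding"
  )
}

#' @export
print.cue_coding <- function(x, ...) {
  cat(
    "<cue_coding> nested numerosity cues",
    if (x$features) {
      paste0(" + features (", paste(x$dimensions, collapse = ", "), ")")
    } else {
      ", numerosity only"
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Encode an object set as a cue set
#'
#' Translates one object set into the cues available to the learner:
#' nested numerosity cues `num1 .. numN` for a set of `set_size` objects,
#' plus one `dimension:value` cue per enabled feature dimension.
#' Deterministic.
#'
#' @param set_size Number of objects in the set, 1--20.
#' @param color,shape,size Feature values of the set's objects (single
#'   categorical values; every object in a set shares them). Required for the
#'   dimensions enabled in `coding`, ignored otherwise.
#' @param coding A [cue_coding()] object.
#' @return Character vector of cue identifiers.
#' @examples
#' encode_set(1, coding = cue_coding(features = FALSE)) # "num1"
#' encode_set(3, color = "red", shape = "round", size = "small")
#' @export
encode_set <- function(set_size, color = NULL, shape = NULL, size = NULL,
                       coding = cue_coding()) {
  stopifnot(inherits(coding, "cue_coding"))
  set_size <- as.integer(set_size)
  if (length(set_size) != 1 || is.na(set_size) || set_size < 1 || set_size > 20) {
    stop("`set_size` must be a single integer in 1..20", call. = FALSE)
  }
  cues <- paste0("num", seq_len(set_size))
  if (coding$features) {
    vals <- list(color = color, shape = shape, size = size)
    for (dim in coding$dimensions) {
      v <- vals[[dim]]
      if (is.null(v) || is.na(v)) {
        stop("feature dimension `", dim, "` enabled but no value given",
          call. = FALSE
        )
      }
      cues <- c(cues, paste0(dim, ":", v))
    }
  }
  cues
}
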