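#' Spoken frequencies of the number words one to seven
#'
#' Per-million-word token frequencies of the number words 1--7 used
#' prenominally, from the 385-million-word Corpus of Contemporary American
#' English and the 100-million-word Corpus del Espanol. The Spanish entry
#' for 1 is a weighted estimate (number-word+noun sequences : tokens of the
#' word), because "uno/una" is gendered and "una" is not used exclusively
#' as a number word; it is carried exactly as published. Frequency of
#' mention is taken as an index of how relevant sets of each size are in a
#' child's environment.
#'
#' @param language `"both"` (default), `"english"` or `"spanish"`.
#' @return A tibble with columns `language`, `number`, `per_million`,
#'   ordered by language then number.
#' @examples
#' number_word_frequencies()
#' @export
number_word_frequencies <- function(language = c("both", "english", "spanish")) {
  language <- match.arg(language)
  path <- system.file("extdata", "number_word_frequencies.tsv",
    package = "numlearn", mustWork = TRUE
  )
  wide <- utils::read.delim(path, check.names = FALSE)
  long <- tibble::tibble(
    language = rep(c("english", "spanish"), each = nrow(wide)),
    number = rep(as.integer(wide$number), 2),
    per_million = c(wide$english_per_million, wide$spanish_per_million)
  )
  if (language != "both") long <- long[long$language == language, ]
  long
}

#' Relative frequencies of number words
#'
#' Normalises per-million frequencies to proportions within each language,
#' so proportions sum to 1 over the numbers present.
#'
#' @param freqs A tibble as from [number_word_frequencies()], with columns
#'   `language`, `number`, `per_million`.
#' @return The input with an added `proportion` column.
#' @examples
#' relative_frequencies(number_word_frequencies("english"))
#' @export
relative_frequencies <- function(freqs) {
  stopifnot(all(c("language", "number", "per_million") %in% names(freqs)))
  if (any(freqs$per_million < 0)) stop("negative frequency", call. = FALSE)
  out <- freqs |>
    dplyr::group_by(.data$language) |>
    dplyr::mutate(proportion = .data$per_million / sum(.data$per_million)) |>
    dplyr::ungroup()
  if (any(!is.finite(out$proportion))) {
    stop("zero total frequency in at least one language", call. = FALSE)
  }
  out
}

#' Cross-language correlation of number-word frequencies
#'
#' Pearson product-moment correlation between the two languages'
#' number-word frequency profiles over the shared number domain. By default
#' the correlation is computed on relative frequencies; because Pearson r is
#' invariant to rescaling either vector, computing it on the raw per-million
#' counts gives the same value, and that route is exposed as an option.
#'
#' @param freqs A tibble as from [number_word_frequencies()] containing
#'   exactly two languages over the same numbers.
#' @param on `"relative"` (default) or `"raw"`.
#' @return A single numeric: Pearson r.
#' @examples
#' crosslang_correlation(number_word_frequencies())
#' @export
crosslang_correlation <- function(freqs, on = c("relative", "raw")) {
  on <- match.arg(on)
  langs <- unique(freqs$language)
  if (length(langs) != 2) {
    stop("`freqs` must contain exactly two languages", call. = FALSE)
  }
  wide <- freqs |>
    dplyr::arrange(.data$number) |>
    tidyr::pivot_wider(
      id_cols = "number", names_from = "language",
      values_from = "per_million"
    )
  x <- wide[[langs[1]]]
  y <- wide[[langs[2]]]
  if (anyNA(x) || anyNA(y)) {
    stop("the two languages must cover the same numbers", call. = FALSE)
  }
  if (on == "relative") {
    x <- x / sum(x)
    y <- y / sum(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant frequency vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Fit an inverse power function to number-word frequencies
#'
#' Spoken number-word frequency falls off with quantity roughly as an
#' inverse power law, `f(n) = a * n^(-b)`. The fit is ordinary least
#' squares in log-log space (`log f = log a - b log n`), the simplest
#' estimator consistent with a power-law form; the exponent `b` is
#' invariant to rescaling the frequencies.
#'
#' @param freqs A tibble with columns `number` and `per_million` for a
#'   single language (filter [number_word_frequencies()] first), or any
#'   strictly positive frequency table; at least 3 entries.
#' @return An object of class `power_fit` with elements `a`, `b`,
#'   `fit_domain` and the underlying `lm` fit. Supports `predict()`
#'   (frequency at new numbers), `tidy()` and `glance()`.
#' @examples
#' fit <- fit_inverse_power(number_word_frequencies("english"))
#' predict(fit, 8:10)
#' @export
fit_inverse_power <- function(freqs) {
  stopifnot(all(c("number", "per_million") %in% names(freqs)))
  if ("language" %in% names(freqs) && length(unique(freqs$language)) > 1) {
    stop("fit one language at a time", call. = FALSE)
  }
  n <- freqs$number
  f <- freqs$per_million
  if (length(n) < 3) stop("need at least 3 entries to fit", call. = FALSE)
  if (any(f <= 0)) stop("frequencies must be strictly positive (log fit)", call. = FALSE)
  fit <- stats::lm(log(f) ~ log(n))
  structure(
    list(
      a = exp(unname(stats::coef(fit)[1])),
      b = -unname(stats::coef(fit)[2]),
      fit_domain = as.integer(n),
      lm = fit
    ),
    class = "power_fit"
  )
}

#' @export
print.power_fit <- function(x, ...) {
  cat(
    "<power_fit> f(n) = ", signif(x$a, 5), " * n^(-", signif(x$b, 5), "), ",
    "fit on n = ", min(x$fit_domain), "..", max(x$fit_domain), "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict frequencies from an inverse power fit
#'
#' @param object A `power_fit` from [fit_inverse_power()].
#' @param newdata Numeric vector of numbers to predict at.
#' @param ... Unused.
#' @return Predicted frequencies `a * n^(-b)` (always positive).
#' @export
predict.power_fit <- function(object, newdata, ...) {
  stopifnot(is.numeric(newdata), all(newdata > 0))
  object$a * newdata^(-object$b)
}

#' @export
tidy.power_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b)
  )
}

#' @export
glance.power_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(
    r.squared = s$r.squared,
    n = length(x$fit_domain)
  )
}

#' Environmental relevance weights for set sizes
#'
#' Relative frequencies with which sets of each size are named in speech,
#' used to weight training schedules. Sizes 1--7 take the observed spoken
#' English frequencies; sizes beyond 7 (up to 20) are extrapolated from the
#' inverse power fit to the observed 1--7, since published counts do not
#' cover them and the distribution is well described by a power law. The
#' resulting weights decrease strictly with size.
#'
#' @param sizes Integer vector of set sizes in 1--20.
#' @param language Language whose frequencies anchor the weights.
#' @return Numeric vector of positive weights, one per size (relative;
#'   unnormalised per-million scale).
#' @examples
#' natural_weights(1:20)
#' @export
natural_weights <- function(sizes = 1:20, language = c("english", "spanish")) {
  language <- match.arg(language)
  sizes <- as.integer(sizes)
  if (any(sizes < 1) || any(sizes > 20)) {
    stop("sizes must lie in 1..20", call. = FALSE)
  }
  freqs <- number_word_frequencies(language)
  fit <- fit_inverse_power(freqs)
  observed <- stats::setNames(freqs$per_million, freqs$number)
  w <- ifelse(
    sizes %in% freqs$number,
    observed[as.character(sizes)],
    predict(fit, sizes)
  )
  unname(w)
}
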