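#' Plot learning curves of a trajectory
#'
#' One line per cue, facetted by outcome: the predictive value of each cue
#' over training, the raw mapping-value view of learning.
#'
#' @param object An `rw_trajectory` from [rw_train()].
#' @param outcomes Outcomes to facet over; defaults to all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rw_trajectory <- function(object, outcomes = object$outcomes, ...) {
  dat <- tidy.rw_trajectory(object) |>
    dplyr::filter(.data$outcome %in% outcomes)
  ggplot2::ggplot(dat, ggplot2::aes(.data$trial, .data$value, colour = .data$cue)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome)) +
    ggplot2::labs(
      x = "trial", y = "associative value V",
      colour = "cue"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the sequencing-effect simulation
#'
#' Weight curves for the cues to one label under the FL and LF
#' arrangements, side by side -- the classic picture of cue competition
#' devaluing uninformative features in FL while LF retains them.
#'
#' @param object A `sim1_result` from [run_sim1()].
#' @param label Which number word's cue weights to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim1_result <- function(object, label = "six", ...) {
  fl <- tidy.rw_trajectory(object$fl) |>
    dplyr::filter(.data$outcome == label) |>
    dplyr::mutate(arrangement = "FL", channel = .data$cue)
  lf <- tidy.rw_trajectory(object$lf) |>
    dplyr::filter(.data$cue == label) |>
    dplyr::mutate(arrangement = "LF", channel = .data$outcome)
  dat <- dplyr::bind_rows(fl, lf)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$trial, .data$value, colour = .data$channel)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$arrangement)) +
    ggplot2::labs(
      x = "trial", y = "associative value V",
      colour = "cue / feature", title = paste0("Cues to \"", label, "\"")
    ) +
    ggplot2::theme_minimal()
}

#' Plot subitization curves
#'
#' Discrimination score over training for each set size, facetted by arm
#' (natural-frequency vs equal-frequency training).
#'
#' @param object A `sim2_result` from [run_sim2()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim2_result <- function(object, ...) {
  ggplot2::ggplot(
    object$curves,
    ggplot2::aes(.data$trial, .data$score,
      colour = factor(.data$set_size),
      group = .data$set_size
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$arm)) +
    ggplot2::labs(
      x = "trial", y = "discrimination score",
      colour = "set size"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the facilitation simulation
#'
#' Discrimination improvement over the final 18 trials by arm and set
#' size; the untrained odd sizes 5 and 7 improve more under the 2-4-6
#' postnominal blocks than under continued natural-frequency exposure.
#'
#' @param object A `sim3_result` from [run_sim3()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim3_result <- function(object, ...) {
  ggplot2::ggplot(
    object$improvement,
    ggplot2::aes(factor(.data$set_size), .data$improvement, fill = .data$arm)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "set size", y = "improvement in discrimination score",
      fill = "arm"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an inverse power fit over observed frequencies
#'
#' Observed number-word frequencies with the fitted `a * n^(-b)` curve on
#' log-log axes.
#'
#' @param object A `power_fit` from [fit_inverse_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_fit <- function(object, ...) {
  obs <- tibble::tibble(
    number = object$fit_domain,
    per_million = exp(stats::fitted(object$lm) + stats::residuals(object$lm))
  )
  grid <- tibble::tibble(
    number = seq(min(object$fit_domain), max(object$fit_domain), length.out = 100)
  )
  grid$per_million <- predict.power_fit(object, grid$number)
  ggplot2::ggplot(obs, ggplot2::aes(.data$number, .data$per_million)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number", y = "tokens per million words") +
    ggplot2::theme_minimal()
}
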