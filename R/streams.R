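#' Read and write event-stream files
#'
#' A trial stream serializes to a plain-text file with one learning event
#' per line: the comma-separated cues, a tab, then the comma-separated
#' outcomes (the outcome field may be empty for an extinction trial). The
#' reader and writer round-trip exactly.
#'
#' @param trials A tibble with list-columns `cues` and `outcomes`.
#' @param path File path.
#' @return `write_event_stream()` returns `trials` invisibly;
#'   `read_event_stream()` returns a tibble with columns `trial`, `cues`,
#'   `outcomes`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' stream <- tibble::tibble(cues = list(c("A", "B")), outcomes = list("X"))
#' write_event_stream(stream, f)
#' read_event_stream(f)
#' @export
write_event_stream <- function(trials, path) {
  stopifnot(all(c("cues", "outcomes") %in% names(trials)))
  lines <- vapply(
    seq_len(nrow(trials)),
    function(i) {
      paste0(
        paste(trials$cues[[i]], collapse = ","),
        "\t",
        paste(trials$outcomes[[i]], collapse = ",")
      )
    },
    character(1)
  )
  writeLines(lines, path)
  invisible(trials)
}

#' @rdname write_event_stream
#' @export
read_event_stream <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty event-stream file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  split_field <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
  }
  tibble::tibble(
    trial = seq_along(lines),
    cues = lapply(parts, function(p) split_field(p[1])),
    outcomes = lapply(parts, function(p) if (length(p) < 2) character(0) else split_field(p[2]))
  )
}

#' Export a trajectory as tidy TSV
#'
#' Writes the long (trial, cue, outcome, value) form of a trajectory to a
#' tab-separated file, one row per recorded weight per snapshot, ready for
#' downstream curve plotting.
#'
#' @param trajectory An `rw_trajectory` from [rw_train()].
#' @param path File path.
#' @return The tidy tibble that was written, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  out <- tidy.rw_trajectory(trajectory)
  readr::write_tsv(out, path)
  invisible(out)
}
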