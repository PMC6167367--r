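#' Event table for single-subject designs
#'
#' Trial onsets, durations and condition labels, optionally split into runs.
#' Uses the BIDS events dialect: tab-separated columns `onset`, `duration`,
#' `trial_type` and (optionally) `run`.
#'
#' @param onset trial onsets in seconds, non-negative and non-decreasing
#'   within each run.
#' @param duration trial durations in seconds, strictly positive.
#' @param trial_type condition label per trial.
#' @param run run identifier per trial (default: a single run).
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(onset, duration, trial_type, run = 1L) {
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   trial_type = as.character(trial_type),
                   run = rep_len(run, length(onset)),
                   stringsAsFactors = FALSE)
  validate_events(ev)
  class(ev) <- c("event_table", "data.frame")
  ev
}

validate_events <- function(ev) {
  if (any(ev$onset < 0)) stop("onsets must be non-negative", call. = FALSE)
  if (any(ev$duration <= 0)) stop("durations must be positive", call. = FALSE)
  for (r in unique(ev$run)) {
    on <- ev$onset[ev$run == r]
    if (is.unsorted(on))
      stop("onsets must be non-decreasing within run ", r, call. = FALSE)
  }
  tab <- table(ev$trial_type)
  if (any(tab < 2L))
    stop("every condition label must occur at least twice ",
         "(otherwise label permutation is degenerate); offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  invisible(ev)
}

#' Read a BIDS-style events file
#'
#' @param path tab-separated file with columns `onset`, `duration`,
#'   `trial_type` and optionally `run`.
#' @return An [event_table()].
#' @examples
#' ev <- read_events(system.file("extdata", "example_events.tsv",
#'                               package = "lisar"))
#' table(ev$trial_type, ev$run)
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("cannot read events: ", path, call. = FALSE)
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(ev$run)) ev$run <- 1L
  event_table(ev$onset, ev$duration, ev$trial_type, ev$run)
}

#' Write an event table to a BIDS-style TSV file
#'
#' @param events an [event_table()].
#' @param path output path.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
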