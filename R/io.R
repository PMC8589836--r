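# TSV round-trip helpers for traces and event tables. Full-precision TSV
# with header row, '.' decimal, UTF-8.

#' Read and write trace/event tables as TSV
#'
#' Traces are written as TSV with header columns such as `time_s`,
#' `intensity_au` (or `extension_nm`) and `trace_id`; event/pause tables as
#' `start_s`, `end_s`, `class`/`pause_type` etc. Values round-trip at full
#' double precision.
#'
#' @param x A tibble.
#' @param path File path.
#' @return `read_trace_tsv()` returns a tibble; `write_trace_tsv()` its
#'   input, invisibly.
#' @export
write_trace_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Start-to-start dwell times between DNA engagements
#'
#' Extracts the dwell times fitted by the gap-time mixture analysis: the
#' time from the start of the recording to the first engagement, then from
#' each engagement start to the next engagement start, and finally a
#' right-censored dwell from the last engagement start to the end of the
#' recording (no next engagement observed).
#'
#' @param events Event tibble with `start_s` (and optionally `trace_id`).
#' @param observation_time Recording length, seconds.
#' @return Tibble with `gap_s`, `censored`, `trace_id`.
#' @export
engagement_gap_times <- function(events, observation_time) {
  check_positive(observation_time, "observation_time")
  if (nrow(events) == 0) {
    return(tibble(gap_s = observation_time, censored = TRUE,
                  trace_id = NA_integer_))
  }
  if (!("trace_id" %in% names(events))) events$trace_id <- 1L
  split(events$start_s, events$trace_id) |>
    purrr::imap(function(st, id) {
      st <- sort(st)
      if (length(st) == 0) {
        return(tibble(gap_s = observation_time, censored = TRUE,
                      trace_id = id))
      }
      tibble(
        gap_s = c(st[1], diff(st), observation_time - st[length(st)]),
        censored = c(rep(FALSE, length(st)), TRUE),
        trace_id = id
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$gap_s > 0)
}
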