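# Roaming-beat extraction: a beat is one time-stamped state change of an
# artifact's binary presence signal.

#' Construct a beat series
#'
#' @param artifact_id Artifact identifier.
#' @param t Beat times (seconds), strictly increasing.
#' @param direction `"to_base"` (0 to 1) or `"to_mobile"` (1 to 0); must
#'   alternate.
#' @param technology Source technology per beat.
#' @param frame_index Optional non-negative frame indexes (NA when no frame
#'   clock was supplied).
#' @return A data frame of class `beat_series` with columns `artifact_id`,
#'   `t`, `direction`, `technology`, `frame_index`.
#' @export
beat_series <- function(artifact_id, t = numeric(), direction = character(),
                        technology = NA_character_, frame_index = NA_integer_) {
  stopifnot(length(t) == length(direction))
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("beat_series: beat times must be strictly increasing")
  if (!all(direction %in% c("to_base", "to_mobile")))
    stop("beat_series: bad direction")
  if (length(direction) > 1L &&
      any(direction[-1L] == direction[-length(direction)]))
    stop("beat_series: directions must alternate")
  df <- data.frame(artifact_id = rep_len(artifact_id, length(t)), t = t,
                   direction = direction,
                   technology = rep_len(technology, length(t)),
                   frame_index = rep_len(as.integer(frame_index), length(t)),
                   stringsAsFactors = FALSE)
  class(df) <- c("beat_series", "data.frame")
  df
}

#' Extract roaming beats from a binary signal
#'
#' One beat per transition: the 0 to 1 change when the artifact appears on
#' the base location (`to_base`) and the 1 to 0 change when it leaves
#' (`to_mobile`).
#'
#' @param signal A [binary_signal].
#' @return A [beat_series]; `nrow` equals the number of transitions.
#' @export
extract_beats <- function(signal) {
  stopifnot(inherits(signal, "binary_signal"))
  tr <- signal$transitions
  beat_series(signal$artifact_id, tr$t,
              ifelse(tr$state == 1L, "to_base", "to_mobile"),
              technology = signal$technology)
}

#' Frame clock
#'
#' Maps run time to video frame indexes: frame `i` starts at
#' `t0 + i / frame_rate`.
#'
#' @param frame_rate Frames per second (> 0); the deployment camera ran at
#'   2.4 fps.
#' @param t0 Time of frame 0, seconds.
#' @return An object of class `frame_clock`.
#' @export
frame_clock <- function(frame_rate = 2.4, t0 = 0) {
  if (frame_rate <= 0) stop("frame_clock: frame_rate must be > 0")
  structure(list(frame_rate = frame_rate, t0 = t0), class = "frame_clock")
}

#' Link beats to video frame indexes
#'
#' Each beat gains `frame_index = floor((t - t0) * frame_rate)`, i.e. the
#' frame current at the instant of the state change, clamped at 0 (with a
#' warning) for beats before the clock origin.
#'
#' @param series A [beat_series].
#' @param clock A [frame_clock].
#' @return The series with `frame_index` filled in.
#' @export
link_frames <- function(series, clock) {
  stopifnot(inherits(series, "beat_series"), inherits(clock, "frame_clock"))
  idx <- floor((series$t - clock$t0) * clock$frame_rate)
  if (any(idx < 0)) {
    warning("link_frames: ", sum(idx < 0),
            " beat(s) before the frame clock origin; frame_index clamped to 0")
    idx[idx < 0] <- 0
  }
  series$frame_index <- as.integer(idx)
  series
}

#' Merge per-artifact beat series into one chronological stream
#'
#' Global order by time; ties broken by artifact id (lexicographic), and the
#' sort is stable within an artifact.
#'
#' @param series_list List of [beat_series] objects.
#' @return A single data frame of beats (class `beat_series` is dropped since
#'   directions need not alternate across artifacts).
#' @export
merge_beat_streams <- function(series_list) {
  if (inherits(series_list, "beat_series")) series_list <- list(series_list)
  dfs <- lapply(series_list, function(s) {
    stopifnot(inherits(s, "beat_series"))
    as.data.frame(s)
  })
  out <- do.call(rbind, dfs)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(artifact_id = character(), t = numeric(),
                      direction = character(), technology = character(),
                      frame_index = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$t, out$artifact_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export beats to CSV or JSONL
#'
#' @param beats A [beat_series] or merged beat data frame.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- as.data.frame(beats)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' Read a merged beat stream from CSV
#'
#' @param path CSV with columns `t`, `artifact_id`, `direction` and
#'   optionally `technology`, `frame_index`.
#' @return A merged beat data frame ordered by `(t, artifact_id)`.
#' @export
read_beats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "artifact_id", "direction") %in% names(df)))
    stop("read_beats: need columns t, artifact_id, direction")
  if (is.null(df$technology)) df$technology <- NA_character_
  if (is.null(df$frame_index)) df$frame_index <- NA_integer_
  df <- df[order(df$t, df$artifact_id),
           c("artifact_id", "t", "direction", "technology", "frame_index")]
  rownames(df) <- NULL
  df
}
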