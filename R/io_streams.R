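TECHNOLOGIES <- c("rfid", "accelerometer", "vision")

#' Construct a raw sensor stream
#'
#' A raw stream is the time-ordered output of one recognition technology for
#' one artifact, before discretization. Value semantics depend on the
#' technology: RFID streams carry the event codes `"gain"` (tag in range of
#' the base-location antenna) and `"loss"` (tag out of range); accelerometer
#' streams carry non-negative absolute g-force magnitudes; vision streams
#' carry one correlation score per frame.
#'
#' @param artifact_id Character scalar identifying the artifact.
#' @param technology One of `"rfid"`, `"accelerometer"`, `"vision"`.
#' @param t Numeric vector of sample times, seconds from the run origin.
#' @param value Event codes (RFID) or numeric readings, same length as `t`.
#' @return An object of class `raw_stream`.
#' @export
raw_stream <- function(artifact_id, technology, t = numeric(), value = character()) {
  technology <- match.arg(technology, TECHNOLOGIES)
  stopifnot(is.character(artifact_id), length(artifact_id) == 1L,
            length(t) == length(value))
  t <- as.numeric(t)
  if (anyNA(t)) stop("raw_stream: sample times contain NA")
  ord <- order(t)
  structure(list(artifact_id = artifact_id, technology = technology,
                 t = t[ord], value = value[ord]),
            class = "raw_stream")
}

#' @export
print.raw_stream <- function(x, ...) {
  cat(sprintf("<raw_stream> artifact '%s' (%s), %d samples\n",
              x$artifact_id, x$technology, length(x$t)))
  invisible(x)
}

#' Read raw event streams from CSV or JSONL
#'
#' Rows carry the columns/keys `t` (seconds), `artifact_id`, `technology`
#' and `value`. Rows belonging to different artifacts are split into one
#' [raw_stream] each, sorted by time (a stable sort, so equal-time rows keep
#' file order).
#'
#' @param path Path to the file.
#' @param format `"csv"` (header row required, comma separated) or `"jsonl"`
#'   (one JSON record per line).
#' @return A named list of [raw_stream] objects keyed by
#'   `"<artifact_id>/<technology>"`; empty input yields an empty list.
#' @export
read_event_stream <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_event_stream: no such file: ", path)
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("read_event_stream: parse error: ",
                                            conditionMessage(e)))
    if (nrow(df) == 0L) return(structure(list(), names = character()))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(structure(list(), names = character()))
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e)
                        stop(sprintf("read_event_stream: parse error at line %d: %s",
                                     i, conditionMessage(e))))
      rec
    })
    df <- do.call(rbind, lapply(recs, function(r)
      data.frame(t = r$t, artifact_id = r$artifact_id,
                 technology = r$technology, value = as.character(r$value),
                 stringsAsFactors = FALSE)))
  }
  need <- c("t", "artifact_id", "technology", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_event_stream: missing column(s): ", paste(miss, collapse = ", "))
  tnum <- suppressWarnings(as.numeric(df$t))
  if (anyNA(tnum)) {
    bad <- which(is.na(tnum))[1L]
    stop(sprintf("read_event_stream: malformed row at line %d: non-numeric t '%s'",
                 bad + 1L, as.character(df$t)[bad]))
  }
  df$t <- tnum
  keys <- paste(df$artifact_id, df$technology, sep = "/")
  out <- lapply(split(seq_len(nrow(df)), keys), function(idx) {
    sub <- df[idx, , drop = FALSE]
    tech <- unique(sub$technology)
    if (length(tech) != 1L || !tech %in% TECHNOLOGIES)
      stop("read_event_stream: unknown technology: ", paste(tech, collapse = ","))
    val <- if (tech == "rfid") as.character(sub$value) else {
      v <- suppressWarnings(as.numeric(sub$value))
      if (anyNA(v)) stop("read_event_stream: non-numeric value for ", tech, " stream")
      v
    }
    raw_stream(unique(sub$artifact_id), tech, sub$t, val)
  })
  out[order(names(out))]
}

#' Write raw event streams to CSV or JSONL
#'
#' Inverse of [read_event_stream()]: all rows of all streams are written in
#' global time order (ties kept in stream order).
#'
#' @param streams A [raw_stream] or list of them.
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_event_stream <- function(streams, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (inherits(streams, "raw_stream")) streams <- list(streams)
  rows <- do.call(rbind, lapply(streams, function(s)
    if (length(s$t) == 0L) NULL else
      data.frame(t = s$t, artifact_id = s$artifact_id, technology = s$technology,
                 value = as.character(s$value), stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(t = numeric(), artifact_id = character(),
                       technology = character(), value = character())
  rows <- rows[order(rows$t), , drop = FALSE]
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(rows)))
      writeLines(jsonlite::toJSON(as.list(rows[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Construct a binary presence signal
#'
#' The canonical discretized form of an artifact's behavior: a step function
#' that is 1 while the artifact is recognized on the base location and 0
#' while it is handled / roaming in the setting. Transitions must strictly
#' alternate and be strictly increasing in time.
#'
#' @param artifact_id Artifact identifier.
#' @param t Numeric vector of transition times (seconds).
#' @param state Integer vector of post-transition states (0/1), same length.
#' @param initial_state State before the first transition (default 0: the
#'   artifact has not yet been placed on the base location).
#' @param technology Optional source technology tag.
#' @return An object of class `binary_signal` with a `transitions` data frame.
#' @export
binary_signal <- function(artifact_id, t = numeric(), state = integer(),
                          initial_state = 0L, technology = NA_character_) {
  stopifnot(length(t) == length(state))
  t <- as.numeric(t); state <- as.integer(state)
  if (!all(state %in% c(0L, 1L)) || !initial_state %in% c(0L, 1L))
    stop("binary_signal: states must be 0 or 1")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("binary_signal: transition times must be strictly increasing")
  full <- c(as.integer(initial_state), state)
  if (any(diff(full) == 0L))
    stop("binary_signal: consecutive states must alternate")
  structure(list(artifact_id = artifact_id,
                 transitions = data.frame(t = t, state = state),
                 initial_state = as.integer(initial_state),
                 technology = technology),
            class = "binary_signal")
}

#' @export
print.binary_signal <- function(x, ...) {
  cat(sprintf("<binary_signal> artifact '%s', %d transitions (initial state %d)\n",
              x$artifact_id, nrow(x$transitions), x$initial_state))
  invisible(x)
}

#' Accelerometer discretization parameters
#'
#' @param threshold Magnitude (g) above which the artifact is considered in
#'   motion: crossing it while at rest produces a 1 to 0 state change.
#' @param rest_band_low,rest_band_high Magnitude band (g) regarded as "at
#'   rest"; re-entering the band produces the 0 to 1 change.
#' @param min_dwell Debounce time (seconds): the signal must stay inside the
#'   rest band this long before the return to state 1 is accepted. `0`
#'   reproduces the bare-threshold rule.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(threshold, rest_band_low, rest_band_high,
                           min_dwell = 0) {
  if (rest_band_low > rest_band_high)
    stop("threshold_spec: rest_band_low must be <= rest_band_high")
  if (min_dwell < 0) stop("threshold_spec: min_dwell must be >= 0")
  structure(list(threshold = threshold, rest_band_low = rest_band_low,
                 rest_band_high = rest_band_high, min_dwell = min_dwell),
            class = "threshold_spec")
}

#' Discretize an RFID event stream
#'
#' TagGain events (tag in antenna range) set state 1, TagLoss events set
#' state 0. Repeated announcements of the current state (reader chatter) are
#' collapsed, keeping the first occurrence.
#'
#' @param stream A [raw_stream] with `technology == "rfid"` and values in
#'   `{"gain", "loss"}`.
#' @return A [binary_signal] with `initial_state = 0`.
#' @export
discretize_rfid <- function(stream) {
  stopifnot(inherits(stream, "raw_stream"))
  if (stream$technology != "rfid")
    stop("discretize_rfid: stream technology is ", stream$technology)
  v <- as.character(stream$value)
  bad <- setdiff(unique(v), c("gain", "loss"))
  if (length(bad))
    stop("discretize_rfid: unknown event code(s): ", paste(bad, collapse = ", "))
  cur <- 0L
  tt <- numeric(); ss <- integer()
  for (i in seq_along(v)) {
    s <- if (v[[i]] == "gain") 1L else 0L
    if (s != cur) {
      tt <- c(tt, stream$t[[i]]); ss <- c(ss, s); cur <- s
    }
  }
  binary_signal(stream$artifact_id, tt, ss, initial_state = 0L,
                technology = "rfid")
}

#' Discretize an accelerometer magnitude stream
#'
#' Implements the threshold rule with an optional rest-band debounce. While
#' at rest (state 1) a magnitude above `threshold` switches to state 0 at
#' that sample's time. While in motion (state 0), the first sample back
#' inside the rest band is a candidate return; it is accepted -- stamped at
#' the re-entry time -- once no sample leaves the band for `min_dwell`
#' seconds (samples between the band and the threshold also cancel the
#' candidate). The initial state is 1 if the first sample lies in the rest
#' band, else 0.
#'
#' @param stream A [raw_stream] with `technology == "accelerometer"`.
#' @param spec A [threshold_spec].
#' @return A [binary_signal].
#' @export
discretize_accelerometer <- function(stream, spec) {
  stopifnot(inherits(stream, "raw_stream"), inherits(spec, "threshold_spec"))
  if (stream$technology != "accelerometer")
    stop("discretize_accelerometer: stream technology is ", stream$technology)
  v <- as.numeric(stream$value)
  if (any(v < 0)) stop("discretize_accelerometer: negative magnitude")
  n <- length(v)
  if (n == 0L)
    return(binary_signal(stream$artifact_id, initial_state = 0L,
                         technology = "accelerometer"))
  in_band <- v >= spec$rest_band_low & v <= spec$rest_band_high
  cur <- if (in_band[[1L]]) 1L else 0L
  tt <- numeric(); ss <- integer()
  cand_t <- NA_real_   # pending re-entry time while in state 0
  for (i in seq_len(n)) {
    if (cur == 1L) {
      if (v[[i]] > spec$threshold) {
        tt <- c(tt, stream$t[[i]]); ss <- c(ss, 0L); cur <- 0L
        cand_t <- NA_real_
      }
    } else {
      if (in_band[[i]]) {
        if (is.na(cand_t)) cand_t <- stream$t[[i]]
        if (stream$t[[i]] - cand_t >= spec$min_dwell) {
          tt <- c(tt, cand_t); ss <- c(ss, 1L); cur <- 1L
          cand_t <- NA_real_
        }
      } else {
        cand_t <- NA_real_
      }
    }
  }
  # dwell window still open at end of stream: accept the pending re-entry
  if (cur == 0L && !is.na(cand_t)) {
    tt <- c(tt, cand_t); ss <- c(ss, 1L)
  }
  binary_signal(stream$artifact_id, tt, ss,
                initial_state = if (in_band[[1L]]) 1L else 0L,
                technology = "accelerometer")
}

#' Discretize a per-frame correlation-score stream
#'
#' Scores at or above the threshold are accepted as "artifact recognized on
#' the base location" (state 1), scores below are state 0. Runs of equal
#' state collapse into alternating transitions; each transition keeps the
#' frame's time so the corresponding beat can be mapped back to a frame
#' index.
#'
#' @param stream A [raw_stream] with `technology == "vision"`.
#' @param threshold Acceptance threshold on the correlation score.
#' @return A [binary_signal] with `initial_state = 0`.
#' @export
discretize_scores <- function(stream, threshold) {
  stopifnot(inherits(stream, "raw_stream"))
  if (stream$technology != "vision")
    stop("discretize_scores: stream technology is ", stream$technology)
  v <- as.numeric(stream$value)
  cur <- 0L
  tt <- numeric(); ss <- integer()
  for (i in seq_along(v)) {
    s <- if (v[[i]] >= threshold) 1L else 0L
    if (s != cur) {
      tt <- c(tt, stream$t[[i]]); ss <- c(ss, s); cur <- s
    }
  }
  binary_signal(stream$artifact_id, tt, ss, initial_state = 0L,
                technology = "vision")
}

#' Export a binary signal as CSV
#'
#' @param signal A [binary_signal].
#' @param path Output path; columns `t`, `state`.
#' @return `path`, invisibly.
#' @export
write_binary_signal <- function(signal, path) {
  stopifnot(inherits(signal, "binary_signal"))
  utils::write.csv(signal$transitions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total time a signal spends in state 1
#'
#' Integrates the step function between `from` and `to` (defaults: first and
#' last transition).
#'
#' @param signal A [binary_signal].
#' @param from,to Integration bounds in seconds.
#' @return Seconds at state 1.
#' @export
time_at_base <- function(signal, from = NULL, to = NULL) {
  tr <- signal$transitions
  if (is.null(from)) from <- if (nrow(tr)) tr$t[[1L]] else 0
  if (is.null(to)) to <- if (nrow(tr)) tr$t[[nrow(tr)]] else 0
  ts <- c(from, tr$t[tr$t > from & tr$t < to], to)
  states <- vapply(ts[-length(ts)], function(x) {
    idx <- which(tr$t <= x)
    if (length(idx)) tr$state[[max(idx)]] else signal$initial_state
  }, integer(1))
  sum(diff(ts)[states == 1L])
}
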