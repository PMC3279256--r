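# Context log: append-only store of beats, inferred activities and person
# events, answering the four context facets (identity, location, time,
# activity) and exporting beat-indexed frame representations.
#
# The store is an in-memory environment of data frames with JSONL
# persistence; appends are idempotent on the record's natural key.

#' Open a context store
#'
#' @param run_id Identifier stamped on every record.
#' @return An object of class `context_store`.
#' @export
log_open <- function(run_id = "run1") {
  st <- new.env(parent = emptyenv())
  st$run_id <- run_id
  st$beats <- data.frame(run_id = character(), t = numeric(),
                         artifact_id = character(), direction = character(),
                         technology = character(), frame_index = integer(),
                         instance_id = character(), stringsAsFactors = FALSE)
  st$activities <- data.frame(run_id = character(), instance_id = character(),
                              name = character(), start_t = numeric(),
                              end_t = numeric(), inferred_at = numeric(),
                              n_beats = integer(),
                              satisfied_artifacts = character(),
                              stringsAsFactors = FALSE)
  st$person_events <- data.frame(run_id = character(), t = numeric(),
                                 person_id = character(), event = character(),
                                 stringsAsFactors = FALSE)
  class(st) <- "context_store"
  st
}

#' @export
print.context_store <- function(x, ...) {
  cat(sprintf("<context_store> run '%s': %d beats, %d activities, %d person events\n",
              x$run_id, nrow(x$beats), nrow(x$activities),
              nrow(x$person_events)))
  invisible(x)
}

.append_unique <- function(old, new, keycols) {
  key <- function(df) do.call(paste, c(df[keycols], sep = "\r"))
  new <- new[!key(new) %in% key(old), , drop = FALSE]
  out <- rbind(old, new[, names(old), drop = FALSE])
  list(df = out, added = nrow(new))
}

#' Record beats, inferred activities or person events
#'
#' Accepts a beat table (columns `t`, `artifact_id`, `direction`, ...), an
#' [run_inference()] result (instances plus their counted beats), a single
#' activity-instance row, or a person event
#' `list(person_id =, t =, event = "gain"/"loss")` from the door antenna.
#' Appends are idempotent: a record whose natural key (run, time, id, kind)
#' is already present is skipped.
#'
#' @param store A [log_open()] store.
#' @param item The item to record.
#' @return Number of rows actually added, invisibly.
#' @export
record <- function(store, item) {
  stopifnot(inherits(store, "context_store"))
  added <- 0L
  if (inherits(item, "inference_result")) {
    added <- record(store, item$instances)
    if (nrow(item$instance_beats)) added <- added + record(store, item$instance_beats)
    return(invisible(added))
  }
  if (is.data.frame(item) && all(c("t", "artifact_id") %in% names(item))) {
    df <- item
    df$run_id <- store$run_id
    if (is.null(df$direction)) df$direction <- NA_character_
    if (is.null(df$technology)) df$technology <- NA_character_
    if (is.null(df$frame_index)) df$frame_index <- NA_integer_
    if (is.null(df$instance_id)) df$instance_id <- NA_character_
    res <- .append_unique(store$beats, df, c("run_id", "t", "artifact_id"))
    store$beats <- res$df
    return(invisible(res$added))
  }
  if (is.data.frame(item) && all(c("name", "inferred_at") %in% names(item))) {
    df <- item
    df$run_id <- store$run_id
    res <- .append_unique(store$activities, df,
                          c("run_id", "name", "inferred_at"))
    store$activities <- res$df
    return(invisible(res$added))
  }
  if (is.list(item) && !is.null(item$person_id)) {
    df <- data.frame(run_id = store$run_id, t = item$t,
                     person_id = item$person_id, event = item$event,
                     stringsAsFactors = FALSE)
    res <- .append_unique(store$person_events, df,
                          c("run_id", "t", "person_id"))
    store$person_events <- res$df
    return(invisible(res$added))
  }
  stop("record: unrecognized item")
}

#' Query the context log
#'
#' Returns time-ordered records matching every supplied filter. Beat records
#' derive the location facet from the state after the beat: a `to_base` beat
#' means the artifact is on the base location, `to_mobile` means it is
#' roaming in the setting. The activity facet is the owning instance (NA for
#' beats outside any inferred activity).
#'
#' @param store A context store.
#' @param from,to Optional time range (seconds, inclusive).
#' @param activity Optional activity name filter.
#' @param artifact_id Optional artifact filter.
#' @param kind Optional record kind filter: `"beat"`, `"activity"`,
#'   `"person_event"`.
#' @return Data frame with columns `record_kind`, `run_id`, `t`, `identity`,
#'   `location`, `activity`, `instance_id`.
#' @export
query <- function(store, from = NULL, to = NULL, activity = NULL,
                  artifact_id = NULL, kind = NULL) {
  stopifnot(inherits(store, "context_store"))
  b <- store$beats
  inst_name <- stats::setNames(store$activities$name,
                               store$activities$instance_id)
  rows <- list()
  if (nrow(b)) {
    rows$beat <- data.frame(
      record_kind = "beat", run_id = b$run_id, t = b$t,
      identity = b$artifact_id,
      location = ifelse(b$direction == "to_base", "base", "roaming"),
      activity = ifelse(is.na(b$instance_id), NA_character_,
                        unname(inst_name[b$instance_id])),
      instance_id = b$instance_id, stringsAsFactors = FALSE)
  }
  a <- store$activities
  if (nrow(a)) {
    rows$activity <- data.frame(
      record_kind = "activity", run_id = a$run_id, t = a$inferred_at,
      identity = a$satisfied_artifacts, location = "base",
      activity = a$name, instance_id = a$instance_id,
      stringsAsFactors = FALSE)
  }
  p <- store$person_events
  if (nrow(p)) {
    rows$person <- data.frame(
      record_kind = "person_event", run_id = p$run_id, t = p$t,
      identity = p$person_id,
      location = ifelse(p$event == "gain", "base", "roaming"),
      activity = NA_character_, instance_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(record_kind = character(), run_id = character(),
                         t = numeric(), identity = character(),
                         location = character(), activity = character(),
                         instance_id = character(), stringsAsFactors = FALSE)
  if (!is.null(kind)) out <- out[out$record_kind %in% kind, , drop = FALSE]
  if (!is.null(from)) out <- out[out$t >= from, , drop = FALSE]
  if (!is.null(to)) out <- out[out$t <= to, , drop = FALSE]
  if (!is.null(activity))
    out <- out[!is.na(out$activity) & out$activity %in% activity, , drop = FALSE]
  if (!is.null(artifact_id))
    out <- out[out$record_kind == "beat" & out$identity %in% artifact_id, ,
               drop = FALSE]
  out <- out[order(out$t, out$record_kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export an activity representation as beat-linked frame indexes
#'
#' For each counted beat of the instance, the index of the video frame
#' current at that instant; optionally adds the frame at the episode's
#' temporal midpoint (the illustrative mid-activity image, which is not
#' itself a state change).
#'
#' @param store A context store holding the instance and its beats.
#' @param instance_id Instance to export.
#' @param clock A [frame_clock].
#' @param include_midpoint Add the midpoint frame.
#' @return A `representation_bundle`: the `activity` row, `frames`
#'   (data frame of beat `t` and `frame_index`, time-ordered) and
#'   `midpoint_frame_index` (NA unless requested).
#' @export
export_representation <- function(store, instance_id, clock,
                                  include_midpoint = FALSE) {
  stopifnot(inherits(store, "context_store"), inherits(clock, "frame_clock"))
  a <- store$activities[store$activities$instance_id == instance_id, ,
                        drop = FALSE]
  if (nrow(a) != 1L)
    stop("export_representation: unknown instance_id: ", instance_id)
  b <- store$beats[!is.na(store$beats$instance_id) &
                     store$beats$instance_id == instance_id, , drop = FALSE]
  b <- b[order(b$t), , drop = FALSE]
  idx <- as.integer(pmax(floor((b$t - clock$t0) * clock$frame_rate), 0))
  mid <- NA_integer_
  if (include_midpoint) {
    tm <- (a$start_t + a$end_t) / 2
    mid <- as.integer(max(floor((tm - clock$t0) * clock$frame_rate), 0))
  }
  structure(list(activity = a,
                 frames = data.frame(t = b$t, frame_index = idx),
                 midpoint_frame_index = mid),
            class = "representation_bundle")
}

#' Persist a context store to JSONL
#'
#' One JSON record per line, tagged with its table; [load_store()] restores
#' an equivalent store.
#'
#' @param store A context store.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_store <- function(store, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(jsonlite::toJSON(list(table = "meta", run_id = store$run_id,
                                   schema = 1L), auto_unbox = TRUE), con)
  dump <- function(df, tab) {
    for (i in seq_len(nrow(df))) {
      rec <- as.list(df[i, ])
      rec$table <- tab
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
    }
  }
  dump(store$beats, "beat")
  dump(store$activities, "activity")
  dump(store$person_events, "person_event")
  invisible(path)
}

#' Restore a context store from JSONL
#'
#' @param path File written by [save_store()].
#' @return A `context_store`.
#' @export
load_store <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- lapply(lines[nzchar(lines)], jsonlite::fromJSON)
  tabs <- vapply(recs, `[[`, "", "table")
  meta <- recs[[which(tabs == "meta")[1L]]]
  st <- log_open(meta$run_id)
  fill <- function(tab, target) {
    rs <- recs[tabs == tab]
    if (!length(rs)) return(target)
    df <- do.call(rbind, lapply(rs, function(r) {
      r$table <- NULL
      r[vapply(r, is.null, logical(1))] <- NA
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
    df <- df[, names(target), drop = FALSE]
    for (nm in names(target))   # JSON nulls come back typeless
      df[[nm]] <- switch(class(target[[nm]])[[1L]],
                         numeric = as.numeric(df[[nm]]),
                         integer = as.integer(df[[nm]]),
                         character = as.character(df[[nm]]),
                         df[[nm]])
    rownames(df) <- NULL
    df
  }
  st$beats <- fill("beat", st$beats)
  st$activities <- fill("activity", st$activities)
  st$person_events <- fill("person_event", st$person_events)
  st
}

#' Summarize inferred activities and their beats
#'
#' A deployment-style summary: per activity the number of inferred instances
#' and total counted beats, with a per-artifact beat breakdown.
#'
#' @param store A context store.
#' @param activity Optional activity filter.
#' @return Data frame with `activity`, `artifact_id` (NA on the activity
#'   total row), `inferred` and `n_beats`.
#' @export
report_activity_summary <- function(store, activity = NULL) {
  a <- store$activities
  b <- store$beats[!is.na(store$beats$instance_id), , drop = FALSE]
  if (!is.null(activity)) a <- a[a$name %in% activity, , drop = FALSE]
  out <- list()
  for (nm in sort(unique(a$name))) {
    ids <- a$instance_id[a$name == nm]
    bb <- b[b$instance_id %in% ids, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      activity = nm, artifact_id = NA_character_,
      inferred = length(ids), n_beats = nrow(bb), stringsAsFactors = FALSE)
    if (nrow(bb))
      for (aid in sort(unique(bb$artifact_id)))
        out[[length(out) + 1L]] <- data.frame(
          activity = nm, artifact_id = aid, inferred = NA_integer_,
          n_beats = sum(bb$artifact_id == aid), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(activity = character(), artifact_id = character(),
                      inferred = integer(), n_beats = integer()))
  do.call(rbind, out)
}
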