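# Criteria-driven temporal inference engine.
#
# One tracker per (activity, artifact) pair counts that artifact's roaming
# beats. While counting, the tracker waits at most the activity's maximum
# duration between beats (the waiting interval); once the artifact's beat
# requirement is met its flag is set and the waiting interval collapses to
# the quantum. A parent coordinator emits the activity at the first clock
# tick at which (1) the quantum has elapsed since the last counted beat,
# (2) beat counts are accomplished and (3) the artifact flags are satisfied:
# all of them in strict mode, at least k_required in flexible mode. On
# emission every tracker of that activity resets, so instances of one
# activity never overlap, while different activities run concurrently.

#' Create an idle tracker
#'
#' @param activity Activity name.
#' @param artifact_id Artifact the tracker counts beats for.
#' @return A `tracker_state` list: `phase` (IDLE / COUNTING / SATISFIED),
#'   `beat_count`, `first_beat_t`, `last_beat_t`, `waiting_interval`
#'   (seconds), `flag`, `ready` and the counted `beats`.
#' @export
tracker_new <- function(activity, artifact_id) {
  structure(list(activity = activity, artifact_id = artifact_id,
                 phase = "IDLE", beat_count = 0L,
                 first_beat_t = NA_real_, last_beat_t = NA_real_,
                 waiting_interval = NA_real_, flag = FALSE, ready = FALSE,
                 beats = list()),
            class = "tracker_state")
}

#' Advance one tracker by a beat or clock tick
#'
#' Pure transition function used by [run_inference()]; exported so the
#' per-artifact semantics can be exercised directly. Events are lists
#' `list(type = "beat", t = <sec>, row = <beat record>)` or
#' `list(type = "clock", t = <sec>)` and must arrive in nondecreasing time.
#'
#' Transitions: an idle tracker starts counting at the first beat and loads
#' the waiting interval with the activity's maximum duration. A beat within
#' the waiting interval is counted and refreshes the last-beat time; reaching
#' `min_beats` sets the artifact flag and shrinks the waiting interval to the
#' quantum. A beat arriving after the waiting interval restarts a fresh
#' episode with that beat. A clock tick past the waiting interval aborts an
#' unsatisfied episode; past the quantum it marks a satisfied tracker ready
#' to infer. Beats reaching a satisfied tracker are counted and re-arm the
#' quantum (beat counts above `max_beats` are tolerated).
#'
#' @param state A `tracker_state`.
#' @param spec The [activity_spec] the tracker belongs to.
#' @param event Beat or clock event (see above).
#' @return `list(state = <new state>, emission = <one of "none", "counted",
#'   "satisfied", "restarted", "aborted", "ready">)`.
#' @export
tracker_step <- function(state, spec, event) {
  crit <- spec$criteria[spec$criteria$artifact_id == state$artifact_id, ]
  if (nrow(crit) != 1L)
    stop("tracker_step: artifact ", state$artifact_id,
         " not in criteria of activity ", spec$name)
  min_beats <- crit$min_beats
  wait_full <- spec$t_max * 60
  q <- spec$quantum * 60
  now <- event$t
  if (!is.na(state$last_beat_t) && now < state$last_beat_t)
    stop("tracker_step: ordering error: event at t=", now,
         " precedes last beat at t=", state$last_beat_t)

  count_beat <- function(st, ev) {
    st$beat_count <- st$beat_count + 1L
    st$last_beat_t <- ev$t
    st$beats[[length(st$beats) + 1L]] <- ev$row
    st$ready <- FALSE
    st
  }
  start_episode <- function(st, ev) {
    st$phase <- "COUNTING"; st$beat_count <- 0L
    st$first_beat_t <- ev$t; st$last_beat_t <- ev$t
    st$waiting_interval <- wait_full
    st$flag <- FALSE; st$ready <- FALSE; st$beats <- list()
    count_beat(st, ev)
  }
  satisfy <- function(st) {
    st$phase <- "SATISFIED"; st$flag <- TRUE; st$waiting_interval <- q
    st
  }

  if (event$type == "beat") {
    if (state$phase == "IDLE") {
      state <- start_episode(state, event)
      if (state$beat_count >= min_beats)
        return(list(state = satisfy(state), emission = "satisfied"))
      return(list(state = state, emission = "counted"))
    }
    if (state$phase == "COUNTING") {
      if (now <= state$last_beat_t + state$waiting_interval) {
        state <- count_beat(state, event)
        if (state$beat_count >= min_beats)
          return(list(state = satisfy(state), emission = "satisfied"))
        return(list(state = state, emission = "counted"))
      }
      state <- start_episode(state, event)   # stale episode: beat starts anew
      if (state$beat_count >= min_beats)
        return(list(state = satisfy(state), emission = "satisfied"))
      return(list(state = state, emission = "restarted"))
    }
    # SATISFIED: extra beats keep the episode alive and re-arm the quantum
    state <- count_beat(state, event)
    return(list(state = state, emission = "counted"))
  }

  # clock tick
  if (state$phase == "COUNTING" &&
      now > state$last_beat_t + state$waiting_interval) {
    fresh <- tracker_new(state$activity, state$artifact_id)
    return(list(state = fresh, emission = "aborted"))
  }
  if (state$phase == "SATISFIED" && !state$ready &&
      now >= state$last_beat_t + q) {
    state$ready <- TRUE
    return(list(state = state, emission = "ready"))
  }
  list(state = state, emission = "none")
}

# first grid multiple of `tick` that is >= x (resp. strictly > x)
.grid_ge <- function(x, tick) tick * ceiling(x / tick - 1e-9)
.grid_gt <- function(x, tick) {
  g <- tick * ceiling(x / tick + 1e-9)
  if (g <= x + 1e-9) g + tick else g
}

.beat_row <- function(df, i) {
  list(artifact_id = df$artifact_id[[i]], t = df$t[[i]],
       direction = if (is.null(df$direction)) NA_character_ else df$direction[[i]],
       technology = if (is.null(df$technology)) NA_character_ else df$technology[[i]],
       frame_index = if (is.null(df$frame_index)) NA_integer_ else df$frame_index[[i]])
}

#' Run concurrent activity inference over a merged beat stream
#'
#' Maintains one tracker per (activity, artifact); every beat is delivered
#' to each tracker whose activity involves that artifact, so beats are
#' non-exclusive across activities. Between beats a virtual clock on a
#' `tick`-second grid advances the trackers, aborting stale episodes and
#' emitting activities whose criteria are met. At emission the episode span
#' (last counted beat minus first) must not exceed the activity's maximum
#' duration; a ready episode that violates it is discarded. If several
#' activities become inferable at the same tick all are emitted, ordered by
#' activity name. Beats for artifacts unknown to every activity are logged
#' and ignored.
#'
#' @param beat_stream Merged beat data frame (see [merge_beat_streams()]),
#'   nondecreasing in `t`.
#' @param specs List of [activity_spec] objects (e.g. from [load_criteria()]).
#' @param tick Clock resolution in seconds (> 0), default 1.
#' @return An object of class `inference_result`: `instances` (data frame
#'   with `instance_id`, `name`, `start_t`, `end_t`, `inferred_at`,
#'   `n_beats`, `satisfied_artifacts`), `instance_beats` (the counted beats
#'   of each instance) and `log` (tracker events).
#' @export
run_inference <- function(beat_stream, specs, tick = 1) {
  stopifnot(tick > 0)
  df <- as.data.frame(beat_stream)
  n <- nrow(df)
  if (n > 1L && any(diff(df$t) < 0))
    stop("run_inference: ordering error: beat stream not sorted by t")
  if (inherits(specs, "activity_spec")) specs <- list(specs)
  specs <- specs[order(vapply(specs, `[[`, "", "name"))]
  names(specs) <- vapply(specs, `[[`, "", "name")

  trackers <- list()
  for (sp in specs)
    for (aid in sp$criteria$artifact_id)
      trackers[[paste(sp$name, aid, sep = "\r")]] <- tracker_new(sp$name, aid)
  tkeys <- names(trackers)
  t_act <- vapply(strsplit(tkeys, "\r", fixed = TRUE), `[[`, "", 1L)
  t_aid <- vapply(strsplit(tkeys, "\r", fixed = TRUE), `[[`, "", 2L)
  known <- unique(t_aid)

  log <- list()
  note <- function(t, ev, activity = NA, artifact = NA)
    log[[length(log) + 1L]] <<- data.frame(t = t, event = ev,
                                           activity = activity,
                                           artifact_id = artifact,
                                           stringsAsFactors = FALSE)
  instances <- list()
  inst_beats <- list()

  emit_or_discard <- function(act, tau) {
    sp <- specs[[act]]
    idx <- which(t_act == act)
    sat <- idx[vapply(idx, function(k) trackers[[k]]$flag, logical(1))]
    if (length(sat) < sp$k_required) return(FALSE)
    t_last <- max(vapply(sat, function(k) trackers[[k]]$last_beat_t, numeric(1)))
    if (tau < t_last + sp$quantum * 60) return(FALSE)
    t_first <- min(vapply(sat, function(k) trackers[[k]]$first_beat_t, numeric(1)))
    if (t_last - t_first <= sp$t_max * 60) {
      beats <- do.call(rbind, lapply(sat, function(k)
        do.call(rbind, lapply(trackers[[k]]$beats, as.data.frame))))
      beats <- beats[order(beats$t, beats$artifact_id), , drop = FALSE]
      id <- sprintf("%s-%03d", act, sum(vapply(instances, function(x)
        x$name == act, logical(1))) + 1L)
      instances[[length(instances) + 1L]] <<- list(
        instance_id = id, name = act, start_t = t_first, end_t = t_last,
        inferred_at = tau, n_beats = nrow(beats),
        satisfied_artifacts = paste(sort(t_aid[sat]), collapse = ";"))
      beats$instance_id <- id
      inst_beats[[length(inst_beats) + 1L]] <<- beats
      note(tau, "inferred", act)
    } else {
      note(tau, "span_exceeded", act)
    }
    for (k in idx) trackers[[k]] <<- tracker_new(act, t_aid[[k]])
    TRUE
  }

  step_clock <- function(tau) {
    for (k in seq_along(trackers)) {
      res <- tracker_step(trackers[[k]], specs[[t_act[[k]]]],
                          list(type = "clock", t = tau))
      trackers[[k]] <<- res$state
      if (res$emission == "aborted") note(tau, "aborted", t_act[[k]], t_aid[[k]])
    }
    for (act in names(specs)) emit_or_discard(act, tau)
  }

  next_deadline <- function() {
    best <- Inf
    for (k in seq_along(trackers)) {
      st <- trackers[[k]]
      d <- if (st$phase == "COUNTING")
        .grid_gt(st$last_beat_t + st$waiting_interval, tick)
      else if (st$phase == "SATISFIED" && !st$ready)
        .grid_ge(st$last_beat_t + specs[[t_act[[k]]]]$quantum * 60, tick)
      else Inf
      if (d < best) best <- d
    }
    best
  }

  deliver_beat <- function(i) {
    aid <- df$artifact_id[[i]]
    if (!aid %in% known) {
      note(df$t[[i]], "unknown_artifact", artifact = aid)
      return(invisible())
    }
    row <- .beat_row(df, i)
    for (k in which(t_aid == aid)) {
      res <- tracker_step(trackers[[k]], specs[[t_act[[k]]]],
                          list(type = "beat", t = df$t[[i]], row = row))
      trackers[[k]] <<- res$state
      if (res$emission == "satisfied")
        note(df$t[[i]], "flag_set", t_act[[k]], aid)
    }
  }

  i <- 1L
  while (i <= n) {
    repeat {
      d <- next_deadline()
      if (d >= df$t[[i]]) break   # tick at a beat's time runs after the beat
      step_clock(d)
    }
    deliver_beat(i)
    i <- i + 1L
  }
  repeat {
    d <- next_deadline()
    if (!is.finite(d)) break
    step_clock(d)
  }

  inst_df <- if (length(instances)) do.call(rbind, lapply(instances, as.data.frame))
             else data.frame(instance_id = character(), name = character(),
                             start_t = numeric(), end_t = numeric(),
                             inferred_at = numeric(), n_beats = integer(),
                             satisfied_artifacts = character())
  if (nrow(inst_df)) {
    inst_df <- inst_df[order(inst_df$inferred_at, inst_df$name), , drop = FALSE]
    rownames(inst_df) <- NULL
  }
  structure(list(
    instances = inst_df,
    instance_beats = if (length(inst_beats)) do.call(rbind, inst_beats)
                     else data.frame(artifact_id = character(), t = numeric(),
                                     direction = character(),
                                     technology = character(),
                                     frame_index = integer(),
                                     instance_id = character()),
    log = if (length(log)) do.call(rbind, log)
          else data.frame(t = numeric(), event = character(),
                          activity = character(), artifact_id = character())),
    class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> %d instance(s)\n", nrow(x$instances)))
  if (nrow(x$instances)) print(x$instances)
  invisible(x)
}
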