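# Ground-truthed scenario simulation.
#
# Emulates caregiver handling episodes at desk scale: for each scheduled
# activity occurrence, per-artifact presence intervals on the base location
# are realized so that the episode's beat pattern satisfies the activity's
# criteria (counts within the duration window, every post-satisfaction
# inter-beat gap shorter than the quantum so one episode yields one
# inference), then rendered as technology-appropriate raw sensor values.

.DEFAULT_MIX <- c(hygiene = 21, feeding = 23, medications = 16,
                  blood_pressure = 14)
.DEFAULT_TECH <- c(tray = "rfid", bp_device = "accelerometer",
                   pillbox = "rfid", paper_towel = "vision",
                   solution = "rfid", cream = "accelerometer")

#' Default accelerometer discretization parameters used by the simulator
#' @return A [threshold_spec] (threshold 1.3 g, rest band 0.9-1.1 g, no dwell).
#' @export
default_accel_spec <- function() threshold_spec(1.3, 0.9, 1.1, min_dwell = 0)

#' Default vision score threshold used by the simulator
#' @return Acceptance threshold on correlation peak scores.
#' @export
default_vision_threshold <- function() 0.5

#' Scenario configuration
#'
#' Describes the emulated deployment: ten 12-hour days with the activity mix
#' observed in the nursing home (21 hygiene, 23 feeding, 16 medications, 14
#' blood pressure; 74 episodes in total) and medications nested inside
#' feeding episodes, as supplied at breakfast and dinner.
#'
#' @param days Number of days.
#' @param hours_per_day Active hours per day.
#' @param activity_mix Named vector: total episode count per activity.
#' @param technologies Named vector mapping artifact_id to the technology
#'   that senses it (`rfid` / `accelerometer` / `vision`).
#' @param nest_medications Nest medication episodes inside feeding episodes
#'   where possible.
#' @param extra_artifact_prob In flexible activities, probability that each
#'   artifact beyond the required `k_required` is also handled (default 1/3:
#'   7 of the 21 hygiene episodes used all three artifacts).
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(days = 10, hours_per_day = 12,
                            activity_mix = .DEFAULT_MIX,
                            technologies = .DEFAULT_TECH,
                            nest_medications = TRUE,
                            extra_artifact_prob = 1 / 3,
                            seed = 1L) {
  if (any(activity_mix < 0)) stop("scenario_config: negative episode count")
  structure(list(days = days, hours_per_day = hours_per_day,
                 activity_mix = activity_mix, technologies = technologies,
                 nest_medications = nest_medications,
                 extra_artifact_prob = extra_artifact_prob,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Noise configuration
#'
#' @param dropout_prob Probability that each transition-causing event/sample
#'   is deleted.
#' @param spurious_rate Spurious events per hour per artifact (Poisson).
#' @param jitter_sd Gaussian time jitter (seconds) applied to every sample.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(dropout_prob = 0, spurious_rate = 0, jitter_sd = 0) {
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("noise_config: dropout_prob must be in [0, 1]")
  if (spurious_rate < 0 || jitter_sd < 0)
    stop("noise_config: rates must be >= 0")
  structure(list(dropout_prob = dropout_prob, spurious_rate = spurious_rate,
                 jitter_sd = jitter_sd),
            class = "noise_config")
}

# beat times for one artifact within one episode: n beats evenly spaced over
# [0, span] with +-5% gap jitter (first beat pinned at 0)
.beat_times <- function(n, span) {
  if (n == 1L) return(0)
  base <- seq(0, span, length.out = n)
  gap <- span / (n - 1L)
  jit <- c(0, stats::runif(n - 2L, -0.05 * gap, 0.05 * gap), 0)
  sort(base + jit)
}

# realize one episode of `sp` starting at absolute time t0; returns
# data.frame(artifact_id, t)
.realize_episode <- function(sp, t0, dur, extra_prob) {
  crit <- sp$criteria[order(-sp$criteria$min_beats), , drop = FALSE]
  use <- rep(TRUE, nrow(crit))
  if (sp$mode == "flexible" && nrow(crit) > sp$k_required)
    use[(sp$k_required + 1L):nrow(crit)] <-
      stats::runif(nrow(crit) - sp$k_required) < extra_prob
  q <- sp$quantum * 60
  rows <- list()
  for (i in which(use)) {
    m <- crit$min_beats[[i]]
    M <- crit$max_beats[[i]]
    n <- if (!is.na(M) && M == m) m else m + sample.int(3L, 1L) - 1L
    if (!is.na(M)) n <- min(n, M)
    span <- if (i == 1L) dur else min(dur, 0.8 * q)
    # keep post-satisfaction gaps below the quantum so the episode emits once
    if (n > m && span / (n - 1L) >= q) n <- m
    rows[[length(rows) + 1L]] <- data.frame(
      artifact_id = crit$artifact_id[[i]],
      t = t0 + .beat_times(n, span), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a ground-truthed synthetic scenario
#'
#' Schedules the configured number of episodes per activity across the days,
#' realizes each episode's per-artifact beat pattern inside the activity's
#' duration window, optionally nests medication episodes inside feeding
#' episodes, and renders every artifact's presence history as raw sensor
#' samples for its configured technology. Episodes of the same activity are
#' separated by more than the activity's maximum duration, so at zero noise
#' each truth episode yields exactly one inference. Byte-identical output is
#' reproduced for a fixed `cfg$seed`.
#'
#' @param cfg A [scenario_config].
#' @param specs Activity specs (see [load_criteria()]); every activity in
#'   `cfg$activity_mix` must be present.
#' @return List with `streams` (named list of [raw_stream]), `truth`
#'   (`episodes` data frame and per-episode `beats`), and the `cfg`.
#' @export
generate_scenario <- function(cfg, specs) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (inherits(specs, "activity_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, "", "name")
  miss <- setdiff(names(cfg$activity_mix), names(specs))
  if (length(miss))
    stop("generate_scenario: config error: no spec for activity ",
         paste(miss, collapse = ", "))
  for (nm in names(cfg$activity_mix)) {
    sp <- specs[[nm]]
    if (sp$t_max * 60 - 10 <= sp$t_min * 60 + 5)
      stop("generate_scenario: config error: infeasible duration window for ", nm)
  }
  set.seed(cfg$seed)
  day_len <- cfg$hours_per_day * 3600

  # per-day counts: floor + randomly placed remainder
  per_day <- sapply(names(cfg$activity_mix), function(nm) {
    k <- cfg$activity_mix[[nm]]
    v <- rep(k %/% cfg$days, cfg$days)
    r <- k %% cfg$days
    if (r > 0) {
      ix <- sample.int(cfg$days, r)
      v[ix] <- v[ix] + 1L
    }
    v
  })
  per_day <- matrix(per_day, nrow = cfg$days,
                    dimnames = list(NULL, names(cfg$activity_mix)))

  episodes <- list(); beats <- list(); eid <- 0L
  add_episode <- function(nm, df) {
    eid <<- eid + 1L
    id <- sprintf("ep%03d", eid)
    episodes[[eid]] <<- data.frame(episode_id = id, activity = nm,
                                   start_t = min(df$t), end_t = max(df$t),
                                   stringsAsFactors = FALSE)
    df$episode_id <- id
    beats[[eid]] <<- df
    id
  }

  for (d in seq_len(cfg$days)) {
    day0 <- (d - 1L) * 86400
    counts <- per_day[d, ]
    n_feed <- if ("feeding" %in% names(counts)) counts[["feeding"]] else 0L
    n_med <- if ("medications" %in% names(counts)) counts[["medications"]] else 0L
    nested <- if (cfg$nest_medications) min(n_feed, n_med) else 0L

    blocks <- character()
    for (nm in names(counts)) {
      k <- counts[[nm]]
      if (nm == "medications") k <- k - nested
      blocks <- c(blocks, rep(nm, k))
    }
    blocks <- sample(blocks)
    # which feeding blocks carry a nested medication
    feed_ix <- which(blocks == "feeding")
    nest_at <- if (nested > 0L) feed_ix[seq_len(nested)] else integer()

    cursor <- day0 + stats::runif(1, 0, 600)
    for (b in seq_along(blocks)) {
      nm <- blocks[[b]]
      sp <- specs[[nm]]
      lo <- sp$t_min * 60 + 5
      hi <- sp$t_max * 60 - 10
      if (nm == "feeding" && b %in% nest_at) lo <- max(lo, 900)
      dur <- stats::runif(1, lo, hi)
      df <- .realize_episode(sp, cursor, dur, cfg$extra_artifact_prob)
      add_episode(nm, df)
      if (b %in% nest_at) {
        spm <- specs[["medications"]]
        mdur <- stats::runif(1, spm$t_min * 60 + 5,
                             min(spm$t_max * 60 - 10, dur - 150))
        mdf <- .realize_episode(spm, cursor + 120, mdur, cfg$extra_artifact_prob)
        add_episode("medications", mdf)
      }
      cursor <- cursor + dur + sp$quantum * 60 + stats::runif(1, 300, 900)
    }
    if (cursor - day0 > day_len)
      warning("generate_scenario: day ", d, " schedule overruns ",
              cfg$hours_per_day, " active hours")
  }

  episodes <- do.call(rbind, episodes)
  beats <- do.call(rbind, beats)
  .check_truth(episodes, beats, specs)

  streams <- .render_streams(beats, cfg$technologies)
  list(streams = streams,
       truth = list(episodes = episodes, beats = beats),
       cfg = cfg)
}

# generator self-consistency: each episode must satisfy its activity's
# criteria and cannot trigger an early emission
.check_truth <- function(episodes, beats, specs) {
  for (i in seq_len(nrow(episodes))) {
    ep <- episodes[i, ]
    sp <- specs[[ep$activity]]
    b <- beats[beats$episode_id == ep$episode_id, ]
    cnt <- table(b$artifact_id)
    sat <- sp$criteria$artifact_id[
      sp$criteria$min_beats <= as.integer(cnt[sp$criteria$artifact_id]) &
        !is.na(cnt[sp$criteria$artifact_id])]
    if (length(sat) < sp$k_required)
      stop("generate_scenario: config error: infeasible pattern for ",
           ep$activity, " (", ep$episode_id, ")")
    if (ep$end_t - ep$start_t > sp$t_max * 60)
      stop("generate_scenario: config error: episode span exceeds window for ",
           ep$activity)
  }
  invisible(TRUE)
}

# render per-artifact beat times as raw sensor samples
.render_streams <- function(beats, technologies) {
  streams <- list()
  for (aid in sort(unique(beats$artifact_id))) {
    tech <- if (aid %in% names(technologies)) technologies[[aid]] else "rfid"
    ts <- sort(beats$t[beats$artifact_id == aid])
    # global alternation from initial state 0 (artifact starts off the base)
    states <- rep_len(c(1L, 0L), length(ts))
    if (tech == "rfid") {
      streams[[paste(aid, tech, sep = "/")]] <-
        raw_stream(aid, "rfid", ts, ifelse(states == 1L, "gain", "loss"))
      next
    }
    tt <- numeric(); vv <- numeric()
    emit <- function(t, v) { tt <<- c(tt, t); vv <<- c(vv, v) }
    if (tech == "accelerometer") {
      hi_move <- 1.5; hi_burst <- 1.8; rest <- 1.0; hi_mid <- 1.7
      for (i in seq_along(ts)) {
        if (states[[i]] == 1L) {
          emit(ts[[i]] - 1, hi_move)   # carried toward the base
          emit(ts[[i]], rest)
        } else {
          emit(ts[[i]], hi_burst)
        }
        if (i < length(ts)) {
          mid <- (ts[[i]] + ts[[i + 1L]]) / 2
          emit(mid, if (states[[i]] == 1L) rest else hi_mid)
        }
      }
    } else if (tech == "vision") {
      for (i in seq_along(ts)) {
        emit(ts[[i]], if (states[[i]] == 1L) 0.9 else 0.2)
        if (i < length(ts)) {
          mid <- (ts[[i]] + ts[[i + 1L]]) / 2
          emit(mid, if (states[[i]] == 1L) 0.88 else 0.12)
        }
      }
    } else stop("generate_scenario: unknown technology ", tech)
    ord <- order(tt)
    tt <- tt[ord]; vv <- vv[ord]
    keep <- !duplicated(tt)
    streams[[paste(aid, tech, sep = "/")]] <-
      raw_stream(aid, tech, tt[keep], vv[keep])
  }
  streams[order(names(streams))]
}

#' Discretize a set of raw streams and merge their beats
#'
#' Convenience pipeline: applies the technology-appropriate discretizer to
#' every stream, extracts roaming beats and merges them chronologically.
#'
#' @param streams Named list of [raw_stream] objects.
#' @param accel_spec [threshold_spec] for accelerometer streams.
#' @param vision_threshold Score threshold for vision streams.
#' @return Merged beat data frame (see [merge_beat_streams()]).
#' @export
streams_to_beats <- function(streams, accel_spec = default_accel_spec(),
                             vision_threshold = default_vision_threshold()) {
  series <- lapply(streams, function(s) {
    sig <- switch(s$technology,
                  rfid = discretize_rfid(s),
                  accelerometer = discretize_accelerometer(s, accel_spec),
                  vision = discretize_scores(s, vision_threshold))
    extract_beats(sig)
  })
  merge_beat_streams(series)
}

#' Corrupt raw streams with dropout, spurious events and time jitter
#'
#' Dropout deletes transition-causing samples: scanning each stream in time
#' order, a sample whose thresholded class (tag present / at rest / score
#' accepted, judged with the simulator's default thresholds) differs from the
#' last kept sample's class is deleted with probability `dropout_prob`; a
#' deleted sample leaves the kept class unchanged, so at `dropout_prob = 1`
#' the corrupted stream discretizes to no transitions at all. Spurious events
#' are inserted as a Poisson process over each stream's time range. All
#' sample times are jittered by Gaussian noise and re-sorted. Deterministic
#' under `seed`.
#'
#' @param streams Named list of [raw_stream] objects.
#' @param noise A [noise_config].
#' @param seed Integer seed.
#' @return The corrupted list of streams.
#' @export
corrupt <- function(streams, noise, seed = 1L) {
  stopifnot(inherits(noise, "noise_config"))
  set.seed(as.integer(seed))
  acc <- default_accel_spec()
  vis_thr <- default_vision_threshold()
  lapply(streams, function(s) {
    t <- s$t; v <- s$value
    n <- length(t)
    if (n == 0L) return(s)
    # classify samples to find transition-causing ones
    cls <- switch(s$technology,
                  rfid = as.integer(v == "gain"),
                  accelerometer = as.integer(as.numeric(v) >= acc$rest_band_low &
                                               as.numeric(v) <= acc$rest_band_high),
                  vision = as.integer(as.numeric(v) >= vis_thr))
    if (noise$dropout_prob > 0) {
      u <- stats::runif(n)
      keep <- logical(n)
      last <- 0L   # signals start absent / below threshold
      for (i in seq_len(n)) {
        if (cls[[i]] != last && u[[i]] < noise$dropout_prob) {
          keep[[i]] <- FALSE          # dropped: kept class unchanged
        } else {
          keep[[i]] <- TRUE
          last <- cls[[i]]
        }
      }
      t <- t[keep]; v <- v[keep]
    }
    if (noise$spurious_rate > 0 && length(t) > 1L) {
      hours <- (max(t) - min(t)) / 3600
      k <- stats::rpois(1L, noise$spurious_rate * hours)
      if (k > 0L) {
        st <- stats::runif(k, min(t), max(t))
        sv <- switch(s$technology,
                     rfid = sample(c("gain", "loss"), k, replace = TRUE),
                     accelerometer = stats::runif(k, 1.4, 2.0),
                     vision = stats::runif(k, 0.6, 1.0))
        t <- c(t, st); v <- c(v, sv)
      }
    }
    if (noise$jitter_sd > 0) t <- t + stats::rnorm(length(t), 0, noise$jitter_sd)
    raw_stream(s$artifact_id, s$technology, t, v)
  })
}

#' Score inference effectiveness against ground truth
#'
#' Matches inferred instances to truth episodes of the same activity by
#' greedy one-to-one maximal temporal overlap (intersection over the shorter
#' interval, accepted at `overlap_min` or above). Effectiveness is the
#' percentage of recorded (inferred) activity events that match a truth
#' episode; the complementary truth-denominated rate is also reported.
#'
#' @param inferred An [run_inference()] result, or a data frame with columns
#'   `name`, `start_t`, `end_t`.
#' @param truth Truth episodes: the `truth` element of [generate_scenario()]
#'   output, or a data frame with `activity`, `start_t`, `end_t`.
#' @param overlap_min Minimum overlap fraction to accept a match.
#' @param instance_beats Optional per-instance beat table (taken from an
#'   `inference_result` automatically) for the per-artifact beat summary.
#' @return An `effectiveness_report`: `n_truth`, `n_inferred`, `n_correct`,
#'   `effectiveness` (percent, correct / inferred), `effectiveness_vs_truth`
#'   (percent, correct / truth), `per_activity` summary and `matches`.
#' @export
evaluate <- function(inferred, truth, overlap_min = 0.5,
                     instance_beats = NULL) {
  if (inherits(inferred, "inference_result")) {
    instance_beats <- inferred$instance_beats
    inferred <- inferred$instances
  }
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$episodes))
    truth <- truth$episodes
  inf <- as.data.frame(inferred)
  tru <- as.data.frame(truth)
  if (nrow(tru) && is.null(tru$activity)) tru$activity <- tru$name

  ov_frac <- function(a1, a2, b1, b2) {
    inter <- max(0, min(a2, b2) - max(a1, b1))
    shorter <- max(min(a2 - a1, b2 - b1), 1e-9)
    inter / shorter
  }
  matches <- list()
  used_t <- rep(FALSE, nrow(tru))
  used_i <- rep(FALSE, nrow(inf))
  for (nm in unique(tru$activity)) {
    ti <- which(tru$activity == nm)
    ii <- which(inf$name == nm)
    if (!length(ii)) next
    cand <- expand.grid(i = ii, j = ti)
    cand$ov <- mapply(function(i, j)
      ov_frac(inf$start_t[[i]], inf$end_t[[i]],
              tru$start_t[[j]], tru$end_t[[j]]),
      cand$i, cand$j)
    cand <- cand[cand$ov >= overlap_min, , drop = FALSE]
    cand <- cand[order(-cand$ov), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[[r]]; j <- cand$j[[r]]
      if (used_i[[i]] || used_t[[j]]) next
      used_i[[i]] <- TRUE; used_t[[j]] <- TRUE
      matches[[length(matches) + 1L]] <-
        data.frame(activity = nm, inferred_row = i, truth_row = j,
                   overlap = cand$ov[[r]], stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches)
             else data.frame(activity = character(), inferred_row = integer(),
                             truth_row = integer(), overlap = numeric())
  n_correct <- nrow(matches)
  n_inferred <- nrow(inf)
  n_truth <- nrow(tru)

  acts <- sort(unique(c(tru$activity, inf$name)))
  per <- do.call(rbind, lapply(acts, function(nm) {
    nb <- if (!is.null(instance_beats) && nrow(instance_beats)) {
      ids <- inf$instance_id[inf$name == nm]
      sum(instance_beats$instance_id %in% ids)
    } else NA_integer_
    data.frame(activity = nm,
               n_truth = sum(tru$activity == nm),
               n_inferred = sum(inf$name == nm),
               n_correct = sum(matches$activity == nm),
               n_beats = nb, stringsAsFactors = FALSE)
  }))
  per_artifact <- if (!is.null(instance_beats) && nrow(instance_beats)) {
    ib <- merge(instance_beats, inf[, c("instance_id", "name")],
                by = "instance_id")
    stats::aggregate(list(n_beats = ib$t), by = list(activity = ib$name,
                     artifact_id = ib$artifact_id), FUN = length)
  } else NULL

  structure(list(n_truth = n_truth, n_inferred = n_inferred,
                 n_correct = n_correct,
                 effectiveness = if (n_inferred > 0)
                   100 * n_correct / n_inferred else 0,
                 effectiveness_vs_truth = if (n_truth > 0)
                   100 * n_correct / n_truth else 0,
                 per_activity = per, per_artifact = per_artifact,
                 matches = matches),
            class = "effectiveness_report")
}

#' @export
print.effectiveness_report <- function(x, ...) {
  cat(sprintf("<effectiveness_report> %d/%d recorded correct (%.2f%%); %d truth episodes (%.2f%%)\n",
              x$n_correct, x$n_inferred, x$effectiveness,
              x$n_truth, x$effectiveness_vs_truth))
  if (!is.null(x$per_activity)) print(x$per_activity)
  invisible(x)
}
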