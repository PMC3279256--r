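# Activity criteria: which artifacts an activity involves, how many beats
# each must produce, the activity's duration window, and the quantum wait.

#' Construct an activity specification
#'
#' An activity is inferred from per-artifact roaming-beat criteria:
#' 1. the set of artifacts involved;
#' 2. a minimum (optionally bounded) beat count per artifact;
#' 3. a duration window `[t_min, t_max]` (minutes) for the whole episode;
#' 4. a quantum (minutes) of silence after the last beat before the activity
#'    is declared inferred -- by convention equal to `t_min`.
#'
#' In `strict` mode every listed artifact must meet its beat criterion; in
#' `flexible` mode at least `k_required` (default 2) artifacts suffice.
#'
#' @param name Activity name.
#' @param criteria Data frame with columns `artifact_id`, `min_beats` and
#'   optionally `max_beats` (NA = unbounded). `max_beats` is advisory: the
#'   artifact flag is set at `min_beats` and later beats re-arm the quantum.
#' @param t_min,t_max Duration window in minutes, `0 < t_min <= t_max`.
#' @param quantum Quantum in minutes (> 0); defaults to `t_min`.
#' @param mode `"strict"` or `"flexible"`.
#' @param k_required Number of satisfied artifacts required in flexible mode
#'   (between 2 and the number of artifacts).
#' @return An object of class `activity_spec`.
#' @export
activity_spec <- function(name, criteria, t_min, t_max, quantum = t_min,
                          mode = c("strict", "flexible"), k_required = 2L) {
  mode <- match.arg(mode)
  criteria <- as.data.frame(criteria, stringsAsFactors = FALSE)
  if (is.null(criteria$max_beats)) criteria$max_beats <- NA_integer_
  if (!all(c("artifact_id", "min_beats") %in% names(criteria)) ||
      nrow(criteria) < 1L)
    stop(sprintf("activity '%s': criteria need >=1 row with artifact_id and min_beats",
                 name))
  criteria$min_beats <- as.integer(criteria$min_beats)
  criteria$max_beats <- as.integer(criteria$max_beats)
  if (any(criteria$min_beats < 1L))
    stop(sprintf("activity '%s': min_beats must be >= 1", name))
  ok_max <- is.na(criteria$max_beats) | criteria$max_beats >= criteria$min_beats
  if (!all(ok_max))
    stop(sprintf("activity '%s': max_beats must be >= min_beats", name))
  if (anyDuplicated(criteria$artifact_id))
    stop(sprintf("activity '%s': duplicated artifact_id in criteria", name))
  if (!(t_min > 0 && t_min <= t_max))
    stop(sprintf("activity '%s': need 0 < t_min <= t_max", name))
  if (quantum <= 0) stop(sprintf("activity '%s': quantum must be > 0", name))
  if (mode == "strict") {
    k_required <- nrow(criteria)
  } else {
    k_required <- as.integer(k_required)
    if (k_required < 2L || k_required > nrow(criteria))
      stop(sprintf("activity '%s': flexible k_required must be in [2, %d]",
                   name, nrow(criteria)))
  }
  structure(list(name = name, criteria = criteria,
                 t_min = t_min, t_max = t_max, quantum = quantum,
                 mode = mode, k_required = k_required),
            class = "activity_spec")
}

#' @export
print.activity_spec <- function(x, ...) {
  cat(sprintf("<activity_spec> %s (%s, k=%d): %s; window %g-%g min, quantum %g min\n",
              x$name, x$mode, x$k_required,
              paste(sprintf("%s>=%d", x$criteria$artifact_id, x$criteria$min_beats),
                    collapse = ", "),
              x$t_min, x$t_max, x$quantum))
  invisible(x)
}

#' Load activity criteria from a configuration document
#'
#' Reads a YAML or JSON document (or an equivalent nested list) with an
#' `activities` map: each activity supplies its duration window `t_min` /
#' `t_max` (minutes), optional `quantum` (defaults to `t_min`), `mode`,
#' optional `k_required`, and an `artifacts` map of
#' `{min_beats, max_beats}`. The configuration shipped at
#' `system.file("extdata", "criteria-nursing-home.yaml", package = "rbeats")`
#' holds the nursing-home deployment defaults: feeding (tray, 2 beats,
#' 5-50 min), blood pressure (device, 3-4 beats, 5-10 min), hygiene
#' (solution >=3, cream >=3, paper towel >=6, 10-30 min, flexible k=2) and
#' medications (pillbox >=2, 3-5 min).
#'
#' @param config A file path (`.yaml`/`.yml`/`.json`) or a nested list.
#' @return A named list of [activity_spec] objects.
#' @export
load_criteria <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("load_criteria: no such file: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  acts <- config$activities
  if (is.null(acts) || length(acts) == 0L)
    stop("load_criteria: config error: missing or empty 'activities'")
  specs <- lapply(names(acts), function(nm) {
    a <- acts[[nm]]
    for (fld in c("t_min", "t_max"))
      if (is.null(a[[fld]]))
        stop(sprintf("load_criteria: config error: activity '%s' missing '%s'",
                     nm, fld))
    if (is.null(a$artifacts) || length(a$artifacts) == 0L)
      stop(sprintf("load_criteria: config error: activity '%s' has no artifacts", nm))
    crit <- do.call(rbind, lapply(names(a$artifacts), function(aid) {
      c0 <- a$artifacts[[aid]]
      data.frame(artifact_id = aid,
                 min_beats = as.integer(c0$min_beats),
                 max_beats = if (is.null(c0$max_beats)) NA_integer_
                             else as.integer(c0$max_beats),
                 stringsAsFactors = FALSE)
    }))
    activity_spec(nm, crit,
                  t_min = a$t_min, t_max = a$t_max,
                  quantum = if (is.null(a$quantum)) a$t_min else a$quantum,
                  mode = if (is.null(a$mode)) "strict" else a$mode,
                  k_required = if (is.null(a$k_required)) 2L else a$k_required)
  })
  names(specs) <- names(acts)
  specs
}

#' Path to the packaged nursing-home criteria configuration
#'
#' @return File path of the shipped YAML config.
#' @export
default_criteria_path <- function() {
  system.file("extdata", "criteria-nursing-home.yaml", package = "rbeats",
              mustWork = TRUE)
}
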