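# Shared fixtures: the packaged nursing-home criteria and canonical traces.

nursing_specs <- function() {
  load_criteria(default_criteria_path())
}

# the canonical 4-beat blood-pressure trace: place, take, return, remove
bp_trace <- function() {
  beat_series("bp_device", c(0, 60, 360, 420),
              c("to_base", "to_mobile", "to_base", "to_mobile"),
              technology = "rfid")
}

# two-artifact hygiene trace: paper towel 6 beats + solution 3 beats inside
# a 20-minute window
hygiene_trace <- function() {
  merge_beat_streams(list(
    beat_series("paper_towel", c(100, 300, 500, 700, 900, 1100),
                rep(c("to_base", "to_mobile"), 3)),
    beat_series("solution", c(60, 120, 180),
                c("to_base", "to_mobile", "to_base"))))
}

# feeding with a medications episode nested inside the tray interval
interleaved_trace <- function() {
  merge_beat_streams(list(
    beat_series("tray", c(0, 1800), c("to_base", "to_mobile")),
    beat_series("pillbox", c(120, 180, 900, 960),
                rep(c("to_base", "to_mobile"), 2))))
}

# random valid binary signal (alternating transitions at integer times)
random_signal <- function(artifact = "a", n_max = 12, t_max = 5000) {
  n <- sample(0:n_max, 1)
  if (n == 0)
    return(binary_signal(artifact, initial_state = sample(0:1, 1)))
  t <- sort(sample.int(t_max, n))
  init <- sample(0:1, 1)
  states <- rep_len(if (init == 0) c(1L, 0L) else c(0L, 1L), n)
  binary_signal(artifact, t, states, initial_state = init)
}

# random small beat stream over the nursing-home artifacts (integer times,
# aligned with the engine's 1 s tick grid)
random_beat_stream <- function(specs, max_beats_per_artifact = 8,
                               horizon = 4000) {
  arts <- unlist(lapply(specs, function(s) s$criteria$artifact_id))
  rows <- do.call(rbind, lapply(arts, function(a) {
    n <- sample(0:max_beats_per_artifact, 1)
    if (n == 0) return(NULL)
    data.frame(artifact_id = a, t = sort(sample.int(horizon, n)),
               direction = NA_character_, technology = NA_character_,
               frame_index = NA_integer_, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) return(NULL)
  rows <- rows[order(rows$t, rows$artifact_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

expect_same_instances <- function(got, want, tick = 1) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(got) == 0) return(invisible())
  expect_equal(got$name, want$name)
  expect_equal(got$start_t, want$start_t)
  expect_equal(got$end_t, want$end_t)
  expect_equal(got$satisfied_artifacts, want$satisfied_artifacts)
  expect_true(all(abs(got$inferred_at - want$inferred_at) <= tick))
}
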