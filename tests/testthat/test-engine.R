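specs <- NULL
setup_specs <- function() {
  if (is.null(specs)) specs <<- nursing_specs()
  specs
}

test_that("a tracker walks IDLE -> COUNTING -> SATISFIED -> ready", {
  sp <- setup_specs()$blood_pressure   # min 3 beats, window 5-10 min, quantum 5
  st <- tracker_new("blood_pressure", "bp_device")
  expect_equal(st$phase, "IDLE")

  r <- tracker_step(st, sp, list(type = "beat", t = 0, row = list(t = 0)))
  expect_equal(r$emission, "counted")
  expect_equal(r$state$phase, "COUNTING")
  expect_equal(r$state$beat_count, 1L)
  # waiting interval loaded with the activity's maximum duration
  expect_equal(r$state$waiting_interval, 600)

  r <- tracker_step(r$state, sp, list(type = "beat", t = 60, row = list(t = 60)))
  expect_equal(r$emission, "counted")
  r <- tracker_step(r$state, sp, list(type = "beat", t = 360, row = list(t = 360)))
  expect_equal(r$emission, "satisfied")
  expect_true(r$state$flag)
  # once satisfied the waiting interval shrinks to the quantum
  expect_equal(r$state$waiting_interval, 300)

  # a 4th beat re-arms the quantum instead of aborting (max_beats advisory)
  r <- tracker_step(r$state, sp, list(type = "beat", t = 420, row = list(t = 420)))
  expect_equal(r$emission, "counted")
  expect_equal(r$state$beat_count, 4L)

  r2 <- tracker_step(r$state, sp, list(type = "clock", t = 719))
  expect_equal(r2$emission, "none")
  r2 <- tracker_step(r2$state, sp, list(type = "clock", t = 720))
  expect_equal(r2$emission, "ready")
})

test_that("an unsatisfied tracker aborts after the waiting interval", {
  sp <- setup_specs()$blood_pressure
  st <- tracker_step(tracker_new("blood_pressure", "bp_device"), sp,
                     list(type = "beat", t = 0, row = list(t = 0)))$state
  r <- tracker_step(st, sp, list(type = "clock", t = 601))
  expect_equal(r$emission, "aborted")
  expect_equal(r$state$phase, "IDLE")
  expect_equal(r$state$beat_count, 0L)

  # a late beat restarts a fresh episode rather than extending the stale one
  r2 <- tracker_step(st, sp, list(type = "beat", t = 1000, row = list(t = 1000)))
  expect_equal(r2$emission, "restarted")
  expect_equal(r2$state$beat_count, 1L)
  expect_equal(r2$state$first_beat_t, 1000)

  expect_error(tracker_step(st, sp, list(type = "clock", t = -5)),
               "ordering error")
})

test_that("the canonical blood-pressure trace infers once, 5 minutes after its last beat", {
  specs <- setup_specs()
  res <- run_inference(merge_beat_streams(list(bp_trace())), specs, tick = 1)
  expect_equal(nrow(res$instances), 1L)
  inst <- res$instances
  expect_equal(inst$name, "blood_pressure")
  expect_equal(inst$start_t, 0)
  expect_equal(inst$end_t, 420)
  expect_equal(inst$inferred_at, 720)          # last beat + 5 min quantum
  expect_equal(inst$n_beats, 4L)
})

test_that("hygiene infers from two qualifying artifacts but not from one", {
  specs <- setup_specs()
  res <- run_inference(hygiene_trace(), specs)
  expect_equal(nrow(res$instances), 1L)
  expect_equal(res$instances$name, "hygiene")
  expect_equal(res$instances$satisfied_artifacts, "paper_towel;solution")
  expect_equal(res$instances$inferred_at - res$instances$end_t, 600)

  # solution alone satisfies its criterion but k_required = 2 blocks inference
  solo <- merge_beat_streams(list(
    beat_series("solution", c(60, 120, 180),
                c("to_base", "to_mobile", "to_base"))))
  expect_equal(nrow(run_inference(solo, specs)$instances), 0L)

  # flexible sufficiency by subset enumeration: any single artifact never
  # infers, any qualifying pair does
  traces <- list(
    paper_towel = beat_series("paper_towel", seq(0, 1000, by = 200),
                              rep(c("to_base", "to_mobile"), 3)),
    solution = beat_series("solution", c(60, 120, 180),
                           c("to_base", "to_mobile", "to_base")),
    cream = beat_series("cream", c(40, 100, 260),
                        c("to_base", "to_mobile", "to_base")))
  for (one in names(traces))
    expect_equal(nrow(run_inference(merge_beat_streams(traces[one]),
                                    specs)$instances), 0L)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    got <- run_inference(merge_beat_streams(traces[pair]), specs)$instances
    expect_equal(got$name, "hygiene")
  }
})

test_that("strict necessity: removing any required artifact prevents inference", {
  cfg <- list(activities = list(duo = list(
    t_min = 2, t_max = 10, mode = "strict",
    artifacts = list(a = list(min_beats = 2), b = list(min_beats = 2)))))
  duo <- load_criteria(cfg)
  both <- merge_beat_streams(list(
    beat_series("a", c(0, 100), c("to_base", "to_mobile")),
    beat_series("b", c(50, 150), c("to_base", "to_mobile"))))
  expect_equal(nrow(run_inference(both, duo)$instances), 1L)
  for (drop in c("a", "b")) {
    part <- both[both$artifact_id != drop, ]
    expect_equal(nrow(run_inference(part, duo)$instances), 0L)
  }
})

test_that("nested medications are inferred before their enclosing feeding", {
  specs <- setup_specs()
  res <- run_inference(interleaved_trace(), specs)
  inst <- res$instances
  expect_true("medications" %in% inst$name)
  expect_true("feeding" %in% inst$name)
  first_med <- min(inst$inferred_at[inst$name == "medications"])
  feed <- inst$inferred_at[inst$name == "feeding"]
  expect_lt(first_med, feed)
  # the feeding tray span is intact despite the interleaving
  expect_equal(inst$start_t[inst$name == "feeding"], 0)
  expect_equal(inst$end_t[inst$name == "feeding"], 1800)
})

test_that("after an aborted episode a full valid episode infers exactly once", {
  specs <- setup_specs()
  # one stray beat, then > t_max of silence, then the canonical trace
  stray <- beat_series("bp_device", 0, "to_base")
  full <- beat_series("bp_device", c(2000, 2060, 2360, 2420),
                      c("to_base", "to_mobile", "to_base", "to_mobile"))
  res <- run_inference(merge_beat_streams(list(stray, full)), specs)
  expect_equal(nrow(res$instances), 1L)
  expect_equal(res$instances$start_t, 2000)
  expect_true("aborted" %in% res$log$event)
})

test_that("episodes longer than the activity window are discarded at emission", {
  cfg <- list(activities = list(slow = list(
    t_min = 1, t_max = 5, mode = "strict",
    artifacts = list(a = list(min_beats = 3)))))
  sp <- load_criteria(cfg)
  # beats each within the waiting interval but spanning 9 min > t_max
  tr <- beat_series("a", c(0, 270, 540), c("to_base", "to_mobile", "to_base"))
  res <- run_inference(merge_beat_streams(list(tr)), sp)
  expect_equal(nrow(res$instances), 0L)
  expect_true("span_exceeded" %in% res$log$event)
})

test_that("beats for unknown artifacts are logged and ignored", {
  specs <- setup_specs()
  st <- merge_beat_streams(list(bp_trace(), beat_series("ghost", 5, "to_base")))
  res <- run_inference(st, specs)
  expect_equal(nrow(res$instances), 1L)
  expect_true(any(res$log$event == "unknown_artifact" &
                    res$log$artifact_id == "ghost"))
  expect_error(run_inference(st[rev(seq_len(nrow(st))), ], specs),
               "ordering error")
})

test_that("emission lags the last counted beat by the quantum, within one tick", {
  specs <- setup_specs()
  q <- stats::setNames(vapply(specs, function(s) s$quantum * 60, numeric(1)),
                       vapply(specs, `[[`, "", "name"))
  set.seed(53)
  for (rep in 1:40) {
    st <- random_beat_stream(specs)
    if (is.null(st)) next
    inst <- run_inference(st, specs, tick = 1)$instances
    if (!nrow(inst)) next
    expect_true(all(abs(inst$inferred_at - inst$end_t - q[inst$name]) <= 1))
    expect_true(all(inst$start_t <= inst$end_t))
    expect_true(all(inst$end_t < inst$inferred_at))
  }
})

test_that("results are a pure function of the stream (order independence)", {
  specs <- setup_specs()
  set.seed(59)
  st <- NULL
  while (is.null(st) || nrow(st) < 10) st <- random_beat_stream(specs)
  a <- run_inference(st, specs)
  # shuffling rows and re-sorting with the canonical tie-break is a no-op
  st2 <- st[sample(nrow(st)), ]
  st2 <- st2[order(st2$t, st2$artifact_id), ]
  b <- run_inference(st2, specs)
  expect_equal(a$instances, b$instances)
  # delivering the specs in reverse order does not change the result
  c <- run_inference(st, rev(specs))
  expect_equal(a$instances, c$instances)
})

test_that("activities inferable at the same tick are all emitted, by name", {
  cfg <- list(activities = list(
    beta = list(t_min = 1, t_max = 5,
                artifacts = list(a = list(min_beats = 2))),
    alpha = list(t_min = 1, t_max = 5,
                 artifacts = list(b = list(min_beats = 2)))))
  sp <- load_criteria(cfg)
  st <- merge_beat_streams(list(
    beat_series("a", c(0, 30), c("to_base", "to_mobile")),
    beat_series("b", c(10, 30), c("to_base", "to_mobile"))))
  inst <- run_inference(st, sp)$instances
  expect_equal(nrow(inst), 2L)
  expect_equal(inst$inferred_at, c(90, 90))
  expect_equal(inst$name, c("alpha", "beta"))
})
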