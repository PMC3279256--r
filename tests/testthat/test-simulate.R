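test_that("a single zero-noise blood-pressure episode discretizes to 4 beats", {
  specs <- nursing_specs()
  cfg <- scenario_config(days = 1, activity_mix = c(blood_pressure = 1),
                         technologies = c(bp_device = "rfid"), seed = 101)
  sc <- generate_scenario(cfg, specs)
  expect_equal(nrow(sc$truth$episodes), 1L)
  beats <- streams_to_beats(sc$streams)
  expect_true(nrow(beats) %in% c(3L, 4L))        # 3-4 beats per the criteria
  expect_equal(nrow(beats), nrow(sc$truth$beats))
  expect_equal(beats$t, sort(sc$truth$beats$t))
  inst <- run_inference(beats, specs)$instances
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$name, "blood_pressure")
})

test_that("scenario generation is byte-identical under a fixed seed", {
  specs <- nursing_specs()
  cfg <- scenario_config(days = 2,
                         activity_mix = c(hygiene = 3, feeding = 4,
                                          medications = 3, blood_pressure = 2),
                         seed = 7)
  a <- generate_scenario(cfg, specs)
  b <- generate_scenario(cfg, specs)
  expect_identical(a$streams, b$streams)
  expect_identical(a$truth, b$truth)
  # and a different seed changes the realization
  c <- generate_scenario(scenario_config(days = 2,
                                         activity_mix = cfg$activity_mix,
                                         seed = 8), specs)
  expect_false(identical(a$truth$beats$t, c$truth$beats$t))
})

test_that("the emulated deployment mix yields 74 truth episodes", {
  specs <- nursing_specs()
  sc <- generate_scenario(scenario_config(seed = 5), specs)
  expect_equal(nrow(sc$truth$episodes), 74L)
  expect_equal(as.vector(table(sc$truth$episodes$activity)[
    c("hygiene", "feeding", "medications", "blood_pressure")]),
    c(21L, 23L, 16L, 14L))
  # every episode's beat pattern satisfies its activity's criteria
  for (i in seq_len(nrow(sc$truth$episodes))) {
    ep <- sc$truth$episodes[i, ]
    sp <- specs[[ep$activity]]
    b <- sc$truth$beats[sc$truth$beats$episode_id == ep$episode_id, ]
    cnt <- table(b$artifact_id)
    ok <- sum(sp$criteria$min_beats <=
                as.integer(cnt[sp$criteria$artifact_id]), na.rm = TRUE)
    expect_gte(ok, sp$k_required)
    expect_lte(ep$end_t - ep$start_t, sp$t_max * 60)
  }
})

test_that("corruption at zero noise is the identity and full dropout silences streams", {
  specs <- nursing_specs()
  sc <- generate_scenario(scenario_config(
    days = 1, activity_mix = c(feeding = 2, blood_pressure = 1),
    seed = 31), specs)
  expect_identical(corrupt(sc$streams, noise_config(0, 0, 0), seed = 1),
                   sc$streams)
  dead <- corrupt(sc$streams, noise_config(dropout_prob = 1), seed = 1)
  expect_equal(nrow(streams_to_beats(dead)), 0L)
})

test_that("dropout deletes about the configured fraction of transition events", {
  # 400 alternating RFID events; sequential dropout at p deletes a fraction
  # p/(1+p) of them in expectation (a deletion shields the next event)
  n <- 400
  s <- list(raw_stream("a", "rfid", seq_len(n),
                       rep_len(c("gain", "loss"), n)))
  p <- 0.1
  fr <- vapply(1:200, function(k)
    1 - length(corrupt(s, noise_config(dropout_prob = p), seed = k)[[1]]$t) / n,
    numeric(1))
  expected <- p / (1 + p)
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se + 1e-6)
  expect_lt(abs(mean(fr) - p), 0.02)   # ~10% of transition events
})

test_that("spurious events and jitter perturb streams reproducibly", {
  s <- list(raw_stream("a", "rfid", seq(0, 7200, by = 600),
                       rep_len(c("gain", "loss"), 13)))
  noisy1 <- corrupt(s, noise_config(0, spurious_rate = 2, jitter_sd = 1),
                    seed = 3)
  noisy2 <- corrupt(s, noise_config(0, spurious_rate = 2, jitter_sd = 1),
                    seed = 3)
  expect_identical(noisy1, noisy2)
  expect_gte(length(noisy1[[1]]$t), 13L)
  expect_false(identical(noisy1[[1]]$t, s[[1]]$t))
  expect_true(!is.unsorted(noisy1[[1]]$t))
})

test_that("effectiveness arithmetic matches the correct/recorded convention", {
  # 74 matching pairs plus 7 unmatched inferences: 74 of 81 recorded
  truth <- data.frame(activity = "feeding",
                      start_t = (0:73) * 4000,
                      end_t = (0:73) * 4000 + 1800)
  inferred <- data.frame(name = "feeding",
                         start_t = c((0:73) * 4000, 7:13 * 1e6),
                         end_t = c((0:73) * 4000 + 1800, 7:13 * 1e6 + 1800))
  rep <- evaluate(inferred, truth)
  expect_equal(rep$n_truth, 74L)
  expect_equal(rep$n_inferred, 81L)
  expect_equal(rep$n_correct, 74L)
  expect_equal(rep$effectiveness, 100 * 74 / 81)
  expect_equal(rep$effectiveness_vs_truth, 100)

  exact <- evaluate(data.frame(name = "feeding", start_t = 0, end_t = 100),
                    data.frame(activity = "feeding", start_t = 0, end_t = 100))
  expect_equal(exact$effectiveness, 100)
  none <- evaluate(data.frame(name = character(), start_t = numeric(),
                              end_t = numeric()), truth)
  expect_equal(none$n_inferred, 0L)
  expect_equal(none$effectiveness, 0)
})

test_that("matching is one-to-one and respects the overlap threshold", {
  truth <- data.frame(activity = "hygiene", start_t = c(0, 1000),
                      end_t = c(600, 1600))
  # one inference overlapping both truths can only match one
  inferred <- data.frame(name = "hygiene", start_t = 300, end_t = 1300)
  rep <- evaluate(inferred, truth, overlap_min = 0.3)
  expect_equal(rep$n_correct, 1L)
  # insufficient overlap is not a match
  rep2 <- evaluate(data.frame(name = "hygiene", start_t = 590, end_t = 1190),
                   truth, overlap_min = 0.5)
  expect_equal(rep2$n_correct, 0L)
  # names must agree
  rep3 <- evaluate(data.frame(name = "feeding", start_t = 0, end_t = 600),
                   truth)
  expect_equal(rep3$n_correct, 0L)
})

test_that("effectiveness does not increase with dropout, in expectation", {
  specs <- nursing_specs()
  mix <- c(hygiene = 2, feeding = 3, medications = 2, blood_pressure = 2)
  eff <- function(p, seed) {
    sc <- generate_scenario(scenario_config(days = 1, activity_mix = mix,
                                            seed = seed), specs)
    beats <- streams_to_beats(corrupt(sc$streams, noise_config(dropout_prob = p),
                                      seed = seed + 1000))
    res <- run_inference(beats, specs)
    evaluate(res, sc$truth)$effectiveness_vs_truth
  }
  seeds <- 1:4
  m0 <- mean(vapply(seeds, function(s) eff(0, s), numeric(1)))
  m2 <- mean(vapply(seeds, function(s) eff(0.25, s), numeric(1)))
  m5 <- mean(vapply(seeds, function(s) eff(0.6, s), numeric(1)))
  expect_gte(m0, m2 - 1e-9)
  expect_gte(m2, m5 - 1e-9)
  expect_equal(m0, 100)
})

test_that("infeasible scenario configurations are rejected", {
  specs <- nursing_specs()
  expect_error(generate_scenario(scenario_config(
    activity_mix = c(bathing = 2), seed = 1), specs), "no spec")
  tight <- load_criteria(list(activities = list(
    blink = list(t_min = 0.05, t_max = 0.2,
                 artifacts = list(a = list(min_beats = 2))))))
  expect_error(generate_scenario(scenario_config(
    activity_mix = c(blink = 1), seed = 1), tight), "config error")
})
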