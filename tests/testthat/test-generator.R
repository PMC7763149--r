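test_that("schedules tile the session and respect dwell bounds", {
  cfg <- generator_config(session_length = 600, seed = 1)
  sch <- sample_schedule(cfg)
  expect_equal(sch$start[1], 0)
  expect_equal(sch$end[nrow(sch)], 600)
  # no gaps, no overlap, time-ordered
  expect_equal(sch$start[-1], sch$end[-nrow(sch)])
  expect_true(all(sch$end > sch$start))
  # no two consecutive identical labels
  expect_true(all(sch$label[-1] != sch$label[-nrow(sch)]))
  # every duration within its label's dwell bounds, except possibly the last
  durs <- sch$end - sch$start
  for (k in seq_len(nrow(sch) - 1)) {
    b <- cfg$behaviours[[sch$label[k]]]
    expect_gte(durs[k], b$dwell_min)
    expect_lte(durs[k], b$dwell_max)
  }
})

test_that("degenerate schedules behave as specified", {
  cfg0 <- generator_config(session_length = 0)
  expect_identical(nrow(sample_schedule(cfg0)), 0L)

  # all weight on rest forces a single repeated label
  cfg <- generator_config(session_length = 300)
  for (nm in names(cfg$behaviours)) cfg$behaviours[[nm]]$relative_frequency <- 0
  cfg$behaviours$rest$relative_frequency <- 1
  expect_true(all(sample_schedule(cfg)$label == "rest"))

  # session shorter than the smallest dwell_min: one truncated event
  cfg2 <- generator_config(session_length = 0.5)
  expect_warning(sch <- sample_schedule(cfg2), "dwell_min")
  expect_identical(nrow(sch), 1L)
  expect_equal(sch$end, 0.5)
})

test_that("streams have the right length, range, and determinism", {
  cfg <- generator_config(session_length = 7, seed = 3)
  sch <- data.frame(event_id = 1L, label = "rest", start = 0, end = 7)
  st <- synthesize_stream(sch, cfg)
  expect_identical(nrow(st), 70L)

  cfg6 <- generator_config(session_length = 600, seed = 11)
  full <- sample_schedule(cfg6)
  s1 <- synthesize_stream(full, cfg6)
  s2 <- synthesize_stream(full, cfg6)
  expect_identical(s1, s2)
  expect_true(all(abs(as.matrix(s1[c("x", "y", "z")])) <=
                    cfg6$device_range))
  # label track and stream cover identical spans
  expect_equal(nrow(s1), round(cfg6$sampling_rate * max(full$end)))
})

test_that("static recovery limit: zero noise and amplitude give pure gravity", {
  cfg <- generator_config(session_length = 10)
  for (nm in names(cfg$behaviours)) {
    cfg$behaviours[[nm]]$noise_sd <- 0
    cfg$behaviours[[nm]]$oscillation_amp <- 0
  }
  sch <- data.frame(event_id = 1L, label = "swim_column", start = 0, end = 10)
  st <- synthesize_stream(sch, cfg)
  expect_equal(st$x, rep(0, 100))
  expect_equal(st$y, rep(0, 100))
  expect_equal(st$z, rep(1, 100))
})

test_that("behaviour signatures: y-variance and ODBA ordering", {
  cfg <- generator_config(session_length = 600, seed = 1)
  sch <- sample_schedule(cfg)
  der_full <- derive_channels(synthesize_stream(sch, cfg))
  epochs <- suppressMessages(segment_epochs(der_full, sch, 2))
  yvar <- tapply(seq_len(nrow(epochs)), epochs$label, function(i) {
    mean(vapply(i, function(k) {
      rows <- seq(epochs$start_index[k], length.out = epochs$n_samples[k])
      stats::var(der_full$y[rows])
    }, 0))
  })
  expect_gt(yvar[["swim_column"]], yvar[["rest"]])
  odba <- tapply(seq_len(nrow(epochs)), epochs$label, function(i) {
    mean(vapply(i, function(k) {
      rows <- seq(epochs$start_index[k], length.out = epochs$n_samples[k])
      mean(der_full$odba[rows])
    }, 0))
  })
  expect_gt(odba[["vertical_swim"]], odba[["swim_column"]])
  expect_gt(odba[["swim_column"]], odba[["rest"]])
})

test_that("generate_dataset writes deterministic, complete sessions", {
  d1 <- file.path(tempdir(), "gen_a"); d2 <- file.path(tempdir(), "gen_b")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- generator_config(session_length = 200, seed = 7)
  generate_dataset(2, cfg, d1)
  generate_dataset(2, cfg, d2)
  expect_setequal(list.files(d1),
                  c("manifest.txt", "session01_accel.csv",
                    "session01_labels.csv", "session02_accel.csv",
                    "session02_labels.csv"))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # four sessions cover all five raw labels at default weights
  d3 <- file.path(tempdir(), "gen_c")
  cfg4 <- generator_config(session_length = 600, seed = 7)
  generate_dataset(4, cfg4, d3)
  labs <- unlist(lapply(read_manifest(file.path(d3, "manifest.txt")),
                        function(s) s$events$label))
  expect_true(all(c("rest", "swim_column", "swim_floor", "vertical_swim",
                    "chew") %in% labs))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(sampling_rate = 0), "sampling_rate")
  cfg <- generator_config()
  cfg$behaviours$rest$baseline_orientation <- c(1, 1, 1)
  expect_error(validate_generator_config(cfg), "unit vector")
  cfg2 <- generator_config()
  cfg2$behaviours$chew$oscillation_freq <- 6
  expect_error(validate_generator_config(cfg2), "Nyquist")
})
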