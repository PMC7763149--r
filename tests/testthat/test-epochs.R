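der_fixture <- function(n = 300, seed = 5)
  derive_channels(make_random_stream(n, seed = seed))

test_that("epoch segmentation tiles events and discards remainders", {
  der <- der_fixture(100)
  ev <- data.frame(event_id = 1:2, label = c("rest", "swim_column"),
                   start = c(0, 7), end = c(7, 8.5))
  ep <- suppressMessages(segment_epochs(der, ev, 2))
  # 70-sample event at 20 samples/epoch: 3 epochs, remainder dropped;
  # 15-sample event: none
  expect_identical(nrow(ep), 3L)
  expect_true(all(ep$event_id == 1))
  expect_equal(ep$start_index, c(1, 21, 41))
  expect_true(all(ep$n_samples == 20))

  # adjacent events never share an epoch
  ev2 <- data.frame(event_id = 1:2, label = c("rest", "swim_column"),
                    start = c(0, 3.5), end = c(3.5, 10))
  ep2 <- segment_epochs(der, ev2, 1)
  for (k in seq_len(nrow(ep2))) {
    rows <- seq(ep2$start_index[k], length.out = ep2$n_samples[k])
    tt <- der$time[rows]
    ev_k <- ev2[ev2$event_id == ep2$event_id[k], ]
    expect_true(all(tt >= ev_k$start - 1e-9 & tt < ev_k$end))
  }

  # excluded labels yield no epochs
  ev3 <- data.frame(event_id = 1:2, label = c("other", "out_of_camera"),
                    start = c(0, 5), end = c(5, 10))
  expect_identical(nrow(segment_epochs(der, ev3, 1)), 0L)
})

test_that("epoch counts follow floor(event_samples / n_samples)", {
  der <- der_fixture(300)
  ev <- data.frame(event_id = 1:3, label = "rest",
                   start = c(0, 10.3, 20), end = c(10.3, 20, 29.9))
  for (eps in c(1, 2)) {
    ep <- suppressMessages(segment_epochs(der, ev, eps))
    n <- eps * 10
    for (k in 1:3) {
      samples <- sum(der$time >= ev$start[k] - 1e-9 &
                       der$time < ev$end[k] - 1e-9)
      expect_identical(sum(ep$event_id == k),
                       as.integer(floor(samples / n)))
    }
  }
})

test_that("summarize_epoch returns exactly the 66 named statistics", {
  der <- der_fixture(60)
  ep <- data.frame(event_id = 1L, label = "rest", start_index = 11,
                   n_samples = 20)
  fv <- summarize_epoch(ep, der)
  feats <- setdiff(names(fv), c("label", "event_id"))
  expect_identical(length(feats), 66L)
  expect_identical(feats, feature_names())
  expect_true(all(is.finite(as.numeric(fv[feats]))))
})

test_that("epoch statistics match textbook re-computation", {
  der <- der_fixture(120, seed = 31)
  ep <- data.frame(event_id = 1L, label = "rest", start_index = 41,
                   n_samples = 20)
  fv <- summarize_epoch(ep, der)
  rows <- 41:60
  for (ch in c("x", "y", "z", "odba", "vedba", "movvar", "energy",
               "pitch", "roll")) {
    o <- oracle_stats(der[[ch]][rows])
    for (s in names(o))
      expect_equal(fv[[paste(ch, s, sep = "_")]], unname(o[s]),
                   tolerance = 1e-12, label = paste(ch, s))
  }
  for (ch in c("odba", "vedba", "movvar", "energy", "pitch", "roll")) {
    expect_equal(fv[[paste0(ch, "_q10")]],
                 oracle_quantile(der[[ch]][rows], 0.1), tolerance = 1e-12)
    expect_equal(fv[[paste0(ch, "_q90")]],
                 oracle_quantile(der[[ch]][rows], 0.9), tolerance = 1e-12)
  }
})

test_that("constant epochs give zero spread and order statistics agree", {
  st <- constant_stream(c(0.3, -0.1, 0.9), n = 20)
  der <- derive_channels(st)
  fv <- summarize_epoch(data.frame(event_id = 1L, label = "rest",
                                   start_index = 1, n_samples = 20), der)
  for (ch in c("x", "y", "z")) {
    expect_equal(fv[[paste0(ch, "_sd")]], 0)
    expect_equal(fv[[paste0(ch, "_skewness")]], 0)
    expect_equal(fv[[paste0(ch, "_kurtosis")]], 0)
    expect_equal(fv[[paste0(ch, "_min")]], fv[[paste0(ch, "_max")]])
    expect_equal(fv[[paste0(ch, "_min")]], fv[[paste0(ch, "_mean")]])
  }
})

test_that("feature vectors satisfy their order invariants", {
  der <- der_fixture(200, seed = 13)
  ev <- data.frame(event_id = 1L, label = "rest", start = 0, end = 20)
  ep <- segment_epochs(der, ev, 2)
  for (k in seq_len(nrow(ep))) {
    fv <- summarize_epoch(ep[k, ], der)
    for (ch in c("x", "y", "odba", "pitch")) {
      expect_lte(fv[[paste0(ch, "_min")]], fv[[paste0(ch, "_mean")]])
      expect_lte(fv[[paste0(ch, "_mean")]], fv[[paste0(ch, "_max")]])
    }
    for (ch in c("odba", "vedba", "movvar", "energy", "pitch", "roll")) {
      expect_lte(fv[[paste0(ch, "_min")]], fv[[paste0(ch, "_q10")]])
      expect_lte(fv[[paste0(ch, "_q10")]], fv[[paste0(ch, "_q90")]])
      expect_lte(fv[[paste0(ch, "_q90")]], fv[[paste0(ch, "_max")]])
    }
  }
})

test_that("build_feature_table respects bounds, ordering and determinism", {
  cfg <- generator_config(session_length = 120, seed = 21)
  sch <- sample_schedule(cfg)
  ses <- list(s1 = list(stream = synthesize_stream(sch, cfg),
                        events = sch))
  t2 <- suppressMessages(build_feature_table(ses, 2))
  t1 <- suppressMessages(build_feature_table(ses, 1))
  expect_lte(nrow(t2), 60)          # at most 120 s / 2 s
  expect_gte(nrow(t1), nrow(t2))    # shorter windows fit at least as often
  expect_identical(ncol(t2), 69L)   # 66 features + label/event_id/session
  t2b <- suppressMessages(build_feature_table(ses, 2))
  expect_identical(t2, t2b)
})
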