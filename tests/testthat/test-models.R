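event_table <- function(events_per_class = 10, rows_per_event = 3) {
  classes <- c("rest", "swim", "vertical_swim", "chew")
  do.call(rbind, lapply(classes, function(cl) {
    do.call(rbind, lapply(seq_len(events_per_class), function(e)
      data.frame(label = cl, event_id = paste0(cl, e),
                 f1 = rnorm(rows_per_event))))
  }))
}

test_that("event splitting is an exact stratified partition", {
  set.seed(1)
  tab <- event_table(10)
  parts <- split_events(tab, 0.8, seed = 5)
  ev <- function(t) unique(t[c("event_id", "label")])
  expect_equal(unname(table(ev(parts$train)$label)), rep(8L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(table(ev(parts$test)$label)), rep(2L, 4),
               ignore_attr = TRUE)
  expect_length(intersect(parts$train$event_id, parts$test$event_id), 0)
  expect_identical(nrow(parts$train) + nrow(parts$test), nrow(tab))

  parts2 <- split_events(tab, 0.8, seed = 5)
  expect_identical(parts, parts2)

  tiny <- rbind(event_table(5),
                data.frame(label = "other", event_id = "other1", f1 = 0))
  expect_warning(p3 <- split_events(tiny, 0.8, seed = 1), "other")
  expect_true("other1" %in% p3$train$event_id)
})

test_that("up-sampling equalises counts with replacement from originals", {
  set.seed(2)
  tab <- rbind(
    data.frame(label = "rest", id = 1:100, f1 = rnorm(100)),
    data.frame(label = "swim", id = 1:150, f1 = rnorm(150)),
    data.frame(label = "chew", id = 1:12, f1 = rnorm(12)),
    data.frame(label = "vertical_swim", id = 1:9, f1 = rnorm(9)))
  up <- upsample_minority(tab, seed = 3)
  expect_true(all(table(up$label) == 150))
  # originals all retained
  expect_identical(up[seq_len(nrow(tab)), ], tab)
  # every duplicated row is bit-identical to some original of its class
  extras <- up[-seq_len(nrow(tab)), ]
  key <- function(d) paste(d$label, d$id, d$f1)
  expect_true(all(key(extras) %in% key(tab)))

  # an already balanced table is returned unchanged
  even <- rbind(data.frame(label = "a", f1 = 1:5),
                data.frame(label = "b", f1 = 6:10))
  expect_identical(upsample_minority(even, seed = 1), even)
  one <- data.frame(label = "a", f1 = 1:5)
  expect_warning(res <- upsample_minority(one), "one class")
  expect_identical(res, one)
})

test_that("separable classes reach near-perfect CV accuracy", {
  tab <- gaussian_two_class(n_per = 60, sep = 6, seed = 3)
  for (nm in c("CART", "SVM")) {
    spec <- model_spec(nm, cv_folds = 3, cv_repeats = 1, quick = TRUE,
                       seed = 9)
    fit <- tune_and_fit(spec, tab)
    expect_gte(fit$cv_accuracy, 0.99)
    expect_gte(fit$cv_kappa, 0.98)
  }
})

test_that("uniformly permuted labels score at chance", {
  set.seed(21)
  tab <- gaussian_two_class(n_per = 120, sep = 4, seed = 4)
  tab$label <- sample(rep(c("a", "b", "c", "d"), each = 60))
  spec <- model_spec("CART", cv_folds = 5, cv_repeats = 1, quick = TRUE,
                     seed = 2)
  fit <- suppressWarnings(tune_and_fit(spec, tab))
  expect_lt(abs(fit$cv_accuracy - 0.25), 0.1)
})

test_that("tuning is deterministic and reports the CV grid", {
  tab <- gaussian_two_class(n_per = 40, sep = 2, seed = 6)
  spec <- model_spec("CART", grid = list(cp = c(0.01, 0.3)), cv_folds = 3,
                     cv_repeats = 2, seed = 17)
  f1 <- tune_and_fit(spec, tab)
  f2 <- tune_and_fit(spec, tab)
  expect_identical(f1$params, f2$params)
  expect_equal(f1$cv_summary, f2$cv_summary)
  expect_identical(nrow(f1$cv_summary), 2L)
  expect_true(all(c("accuracy", "kappa") %in% colnames(f1$cv_summary)))
  p1 <- predict_model(f1, tab)
  expect_identical(p1, predict_model(f2, tab))
})

test_that("stratified folding errors when a class cannot be folded", {
  tab <- gaussian_two_class(n_per = 30, sep = 3, seed = 8)
  tab$label[1] <- "rare"
  tab <- tab[c(1, 31:90), ]
  spec <- model_spec("CART", cv_folds = 3, cv_repeats = 1, quick = TRUE)
  expect_error(tune_and_fit(spec, tab), "rare")
})
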