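MODEL_NAMES <- c("CART", "RF", "SVM", "XGB", "C50", "GBM", "NNET", "AVNNET")

#' Split epochs into train and test sets by whole behaviour events
#'
#' Whole events (all their epochs) are assigned to exactly one side,
#' stratified by class, so no within-event correlation leaks across the
#' split. Per class, the test share is `max(1, round((1 - train_fraction) *
#' n_events))`; a class with fewer than two events goes entirely to train
#' with a warning.
#'
#' @param table feature table with `event_id` and `label` columns.
#' @param train_fraction fraction of events per class in train (default 0.8).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_events <- function(table, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  ev <- unique(table[c("event_id", "label")])
  set.seed(derive_seed(seed, 4))
  test_ids <- character(0)
  for (cl in sort(unique(ev$label))) {
    ids <- ev$event_id[ev$label == cl]
    if (length(ids) < 2) {
      warnf("class '%s' has %d event(s); placed entirely in train", cl,
            length(ids))
      next
    }
    n_test <- max(1L, round((1 - train_fraction) * length(ids)))
    test_ids <- c(test_ids, sample(ids, n_test))
  }
  list(train = table[!(table$event_id %in% test_ids), , drop = FALSE],
       test = table[table$event_id %in% test_ids, , drop = FALSE])
}

#' Up-sample minority classes to the majority count
#'
#' Every class is brought to the majority class's row count by sampling its
#' own rows with replacement; all original rows are retained.
#'
#' @param table training feature table with a `label` column.
#' @param seed integer seed.
#' @return the balanced table.
#' @export
upsample_minority <- function(table, seed = 1L) {
  counts <- table(table$label)
  if (length(counts) < 2) {
    warnf("only one class present; nothing to up-sample")
    return(table)
  }
  target <- max(counts)
  set.seed(derive_seed(seed, 5))
  extras <- lapply(names(counts), function(cl) {
    need <- target - counts[[cl]]
    if (need == 0) return(NULL)
    rows <- which(table$label == cl)
    table[sample(rows, need, replace = TRUE), , drop = FALSE]
  })
  out <- rbind(table, do.call(rbind, extras))
  rownames(out) <- NULL
  out
}

#' Specify one classifier and its tuning protocol
#'
#' @param name one of CART, RF, SVM, XGB, C50, GBM, NNET, AVNNET. C50 and
#'   GBM are boosted-tree configurations flagged `approximate` in reports
#'   (C5.0's rule-based booster and classical stochastic gradient boosting
#'   have no engine here; gradient-boosted trees with matching structure
#'   stand in, GBM with row subsampling 0.5).
#' @param grid named list of hyperparameter value vectors; `NULL` for the
#'   registry default.
#' @param cv_folds,cv_repeats cross-validation protocol (default 10 x 5).
#' @param seed integer seed governing folding, per-fold up-sampling and
#'   fit initialisation.
#' @param quick use the registry's reduced grid (single configuration) —
#'   intended for smoke runs and the bundled end-to-end checks.
#' @return a `model_spec`.
#' @export
model_spec <- function(name, grid = NULL, cv_folds = 10, cv_repeats = 5,
                       seed = 1L, quick = FALSE) {
  name <- match.arg(name, MODEL_NAMES)
  eng <- model_registry[[name]]
  grid <- grid %||% (if (quick) eng$quick_grid else eng$grid)
  if (length(grid) == 0 || any(!lengths(grid)))
    stopf("hyperparameter grid must be non-empty")
  if (cv_folds < 2) stopf("cv_folds must be >= 2")
  structure(list(name = name, grid = grid, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, seed = as.integer(seed),
                 approximate = eng$approximate,
                 standardize = eng$standardize),
            class = "model_spec")
}

#' The eight-model comparison set
#'
#' @param cv_folds,cv_repeats,seed,quick passed to [model_spec()]; `quick`
#'   also lowers folds/repeats to 5/1 unless given explicitly.
#' @param models subset of model names (default all eight).
#' @return named list of `model_spec`s.
#' @export
default_model_specs <- function(models = MODEL_NAMES, cv_folds = NULL,
                                cv_repeats = NULL, seed = 1L,
                                quick = FALSE) {
  cv_folds <- cv_folds %||% (if (quick) 5 else 10)
  cv_repeats <- cv_repeats %||% (if (quick) 1 else 5)
  stats::setNames(lapply(models, model_spec, cv_folds = cv_folds,
                         cv_repeats = cv_repeats, seed = seed,
                         quick = quick), models)
}

# --- engine registry -------------------------------------------------------
# Each engine: fit(x, y, p) -> model object; predict(obj, x) -> character.
# x is a numeric matrix (already standardised for engines that want it),
# y a factor. Fits must be deterministic given the R RNG state.

xgb_fit <- function(x, y, p, subsample = 1) {
  lev <- levels(y)
  d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1)
  m <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(lev),
                  max_depth = p$max_depth, eta = p$eta,
                  subsample = subsample, nthread = 1,
                  seed = sample.int(1e6, 1)),
    data = d, nrounds = p$nrounds, verbose = 0)
  list(model = m, levels = lev)
}
xgb_predict <- function(obj, x) {
  pr <- predict(obj$model, xgboost::xgb.DMatrix(x), reshape = TRUE)
  obj$levels[max.col(matrix(pr, ncol = length(obj$levels)))]
}

nnet_fit_one <- function(x, y, p) {
  nnet::nnet(x, nnet::class.ind(y), size = p$size, decay = p$decay,
             maxit = 200, MaxNWts = 10000, trace = FALSE, softmax = TRUE)
}
nnet_predict_prob <- function(m, x, lev) {
  pr <- predict(m, x)
  colnames(pr) <- lev
  pr
}

model_registry <- list(
  CART = list(
    standardize = FALSE, approximate = FALSE,
    grid = list(cp = c(0.001, 0.01, 0.05)),
    quick_grid = list(cp = 0.01),
    fit = function(x, y, p) {
      df <- data.frame(x, .label = y, check.names = FALSE)
      rpart::rpart(.label ~ ., df, method = "class",
                   control = rpart::rpart.control(cp = p$cp))
    },
    predict = function(obj, x)
      as.character(predict(obj, data.frame(x, check.names = FALSE),
                           type = "class"))),
  RF = list(
    standardize = FALSE, approximate = FALSE,
    grid = list(mtry = c(4, 8, 16, 32), ntree = 500),
    quick_grid = list(mtry = 8, ntree = 300),
    fit = function(x, y, p)
      randomForest::randomForest(x, y, ntree = p$ntree,
                                 mtry = min(p$mtry, ncol(x))),
    predict = function(obj, x) as.character(predict(obj, x))),
  SVM = list(
    standardize = TRUE, approximate = FALSE,
    grid = list(cost = c(0.25, 0.5, 1, 2, 4), gamma_mult = c(0.5, 1, 2)),
    quick_grid = list(cost = 1, gamma_mult = 1),
    fit = function(x, y, p)
      e1071::svm(x, y, kernel = "radial", cost = p$cost, gamma = p$gamma,
                 scale = FALSE),
    predict = function(obj, x) as.character(predict(obj, x))),
  XGB = list(
    standardize = FALSE, approximate = FALSE,
    grid = list(max_depth = c(2, 4, 6), eta = c(0.05, 0.1, 0.3),
                nrounds = c(50, 150)),
    quick_grid = list(max_depth = 4, eta = 0.3, nrounds = 60),
    fit = function(x, y, p) xgb_fit(x, y, p),
    predict = xgb_predict),
  C50 = list(
    standardize = FALSE, approximate = TRUE,
    grid = list(max_depth = c(4, 8), eta = 0.3, nrounds = c(40, 80)),
    quick_grid = list(max_depth = 6, eta = 0.3, nrounds = 50),
    fit = function(x, y, p) xgb_fit(x, y, p),
    predict = xgb_predict),
  GBM = list(
    standardize = FALSE, approximate = TRUE,
    grid = list(max_depth = c(2, 4), eta = c(0.05, 0.1),
                nrounds = c(100, 200)),
    quick_grid = list(max_depth = 3, eta = 0.1, nrounds = 80),
    fit = function(x, y, p) xgb_fit(x, y, p, subsample = 0.5),
    predict = xgb_predict),
  NNET = list(
    standardize = TRUE, approximate = FALSE,
    grid = list(size = c(4, 8, 16), decay = c(1e-4, 1e-2)),
    quick_grid = list(size = 8, decay = 1e-2),
    fit = function(x, y, p)
      list(nets = list(nnet_fit_one(x, y, p)), levels = levels(y)),
    predict = function(obj, x) {
      pr <- nnet_predict_prob(obj$nets[[1]], x, obj$levels)
      obj$levels[max.col(pr)]
    }),
  AVNNET = list(
    standardize = TRUE, approximate = FALSE,
    grid = list(size = c(4, 8, 16), decay = c(1e-4, 1e-2)),
    quick_grid = list(size = 8, decay = 1e-2),
    fit = function(x, y, p)
      list(nets = lapply(1:5, function(i) nnet_fit_one(x, y, p)),
           levels = levels(y)),
    predict = function(obj, x) {
      pr <- Reduce(`+`, lapply(obj$nets, nnet_predict_prob, x = x,
                               lev = obj$levels)) / length(obj$nets)
      obj$levels[max.col(pr)]
    })
)

feature_matrix <- function(table, feats) {
  m <- as.matrix(table[feats])
  storage.mode(m) <- "double"
  m
}

standardize_apply <- function(m, center, scale)
  sweep(sweep(m, 2, center), 2, scale, "/")

# Median-heuristic RBF width on (standardised) training features:
# gamma0 = 1 / (2 * median pairwise distance^2), on <=200 sampled rows.
median_gamma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
  d <- stats::dist(x[idx, , drop = FALSE])
  med <- stats::median(d[d > 0])
  if (!is.finite(med) || med == 0) return(1 / ncol(x))
  1 / (2 * med^2)
}

# Stratified fold assignment: within each class, rows are shuffled and
# dealt round-robin, so every fold holds every class when counts allow.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    if (length(rows) < k && length(rows) < 2)
      stopf("class '%s' has too few rows for %d-fold CV", cl, k)
    fold[rows] <- (sample(seq_along(rows)) %% k) + 1L
  }
  fold
}

#' Tune hyperparameters by repeated CV and fit the final model
#'
#' Grid search scored by mean cross-validated accuracy (Cohen's kappa
#' reported alongside). Folds are stratified by class; the minority classes
#' are up-sampled *inside each CV training fold* (never the held-out fold),
#' so duplicate rows cannot straddle a fold boundary; the winning
#' configuration is refit on the up-sampled full training table. Features
#' are standardised with train-fold statistics for SVM and the neural
#' networks only.
#'
#' @param spec a [model_spec()].
#' @param train_table training feature table (66 features + `label`;
#'   `event_id`/`session` columns are carried, not used as features).
#' @return a `behavacc_fit`: list with the fitted engine object, resolved
#'   hyperparameters, standardisation constants, feature names, class
#'   levels, and `cv_summary` (per-configuration mean accuracy and kappa).
#' @export
tune_and_fit <- function(spec, train_table) {
  stopifnot(inherits(spec, "model_spec"))
  feats <- setdiff(names(train_table), c("label", "event_id", "session"))
  y_all <- factor(train_table$label)
  if (nlevels(y_all) < 2) stopf("need at least two classes to fit")
  x_all <- feature_matrix(train_table, feats)
  eng <- model_registry[[spec$name]]

  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  gamma0 <- NULL
  if (!is.null(grid$gamma_mult)) {
    set.seed(derive_seed(spec$seed, 6))
    xs <- scale(x_all)
    xs[!is.finite(xs)] <- 0
    gamma0 <- median_gamma(xs)
    grid$gamma <- gamma0 * grid$gamma_mult
  }

  scores <- matrix(NA_real_, nrow(grid), 2,
                   dimnames = list(NULL, c("accuracy", "kappa")))
  for (g in seq_len(nrow(grid))) {
    accs <- c(); kaps <- c()
    for (r in seq_len(spec$cv_repeats)) {
      set.seed(derive_seed(spec$seed, 10 + r))
      fold <- stratified_folds(as.character(y_all), spec$cv_folds)
      for (k in seq_len(spec$cv_folds)) {
        tr <- which(fold != k); te <- which(fold == k)
        if (!length(te)) next
        set.seed(derive_seed(spec$seed, 1000 * g + 10 * r + k))
        bal <- upsample_rows(train_table[tr, , drop = FALSE])
        fit1 <- fit_one(eng, spec, bal, feats, as.list(grid[g, , drop = FALSE]))
        pred <- predict_model(fit1, train_table[te, , drop = FALSE])
        cm <- confusion_matrix(pred, as.character(y_all)[te],
                               classes = levels(y_all))
        met <- suppressWarnings(class_metrics(cm))
        accs <- c(accs, met$accuracy); kaps <- c(kaps, met$kappa)
      }
    }
    scores[g, ] <- c(mean(accs), mean(kaps, na.rm = TRUE))
  }
  best <- which.max(scores[, "accuracy"])
  set.seed(derive_seed(spec$seed, 7))
  bal_full <- upsample_rows(train_table)
  fit <- fit_one(eng, spec, bal_full, feats, as.list(grid[best, , drop = FALSE]))
  fit$cv_summary <- cbind(grid, scores)
  fit$cv_accuracy <- scores[best, "accuracy"]
  fit$cv_kappa <- scores[best, "kappa"]
  fit
}

# up-sampling used inside CV folds / final refit (local RNG state)
upsample_rows <- function(table) {
  counts <- table(table$label)
  if (length(counts) < 2) return(table)
  target <- max(counts)
  extras <- lapply(names(counts), function(cl) {
    need <- target - counts[[cl]]
    if (need == 0) return(NULL)
    table[sample(which(table$label == cl), need, replace = TRUE), ,
          drop = FALSE]
  })
  rbind(table, do.call(rbind, extras))
}

fit_one <- function(eng, spec, table, feats, params) {
  y <- factor(table$label)
  x <- feature_matrix(table, feats)
  center <- NULL; scl <- NULL
  if (eng$standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- standardize_apply(x, center, scl)
  }
  obj <- eng$fit(x, y, params)
  structure(list(name = spec$name, engine_fit = obj, params = params,
                 features = feats, levels = levels(y), center = center,
                 scale = scl, approximate = spec$approximate),
            class = "behavacc_fit")
}

#' Predict class labels from a fitted model
#'
#' @param fit a `behavacc_fit` from [tune_and_fit()].
#' @param table feature table holding at least the fit's feature columns.
#' @return character vector of predicted labels.
#' @export
predict_model <- function(fit, table) {
  x <- feature_matrix(table, fit$features)
  if (!is.null(fit$center))
    x <- standardize_apply(x, fit$center, fit$scale)
  model_registry[[fit$name]]$predict(fit$engine_fit, x)
}

#' @export
print.behavacc_fit <- function(x, ...) {
  cat(sprintf("<behavacc_fit> %s%s | classes: %s\n", x$name,
              if (x$approximate) " (approximate engine)" else "",
              paste(x$levels, collapse = ", ")))
  cat("  params:", paste(names(x$params),
                         vapply(x$params, format, ""), sep = "=",
                         collapse = ", "), "\n")
  if (!is.null(x$cv_accuracy))
    cat(sprintf("  CV accuracy %.3f, kappa %.3f\n", x$cv_accuracy,
                x$cv_kappa))
  invisible(x)
}

#' Run the full model-comparison experiment
#'
#' For each epoch length and each model specification: event-level 80/20
#' split, CV tuning on the training events, final fit, and held-out
#' evaluation (confusion matrix, per-class metric set, accuracy, macro-F,
#' kappa). A runtime leakage guard asserts that no event id crosses the
#' partition.
#'
#' @param tables named list of feature tables, e.g.
#'   `list("1" = tab1s, "2" = tab2s)` keyed by epoch seconds.
#' @param specs named list of [model_spec()]s (default all eight, quick
#'   grids off).
#' @param train_fraction,seed split parameters (one split per epoch table).
#' @return an `experiment_result`: list with `comparison` (one row per
#'   epoch x model, sorted by test accuracy within epoch) and `results`
#'   (per epoch/model: fit, confusion matrix, metrics, test event ids).
#' @export
run_experiment <- function(tables, specs = default_model_specs(),
                           train_fraction = 0.8, seed = 1L) {
  results <- list()
  comp <- list()
  for (ep in names(tables)) {
    tab <- tables[[ep]]
    parts <- split_events(tab, train_fraction, seed = seed)
    if (length(intersect(unique(parts$train$event_id),
                         unique(parts$test$event_id))))
      stopf("leakage guard tripped: event id on both sides of the split")
    classes <- sort(unique(tab$label))
    for (nm in names(specs)) {
      fit <- tune_and_fit(specs[[nm]], parts$train)
      pred <- predict_model(fit, parts$test)
      cm <- confusion_matrix(pred, parts$test$label, classes = classes)
      met <- suppressWarnings(class_metrics(cm))
      key <- paste0(nm, "_", ep, "s")
      results[[key]] <- list(epoch_s = as.numeric(ep), model = nm,
                             fit = fit, confusion = cm, metrics = met,
                             test_event_ids = unique(parts$test$event_id))
      comp[[key]] <- data.frame(
        epoch_s = as.numeric(ep), model = nm,
        approximate = fit$approximate,
        cv_accuracy = fit$cv_accuracy, cv_kappa = fit$cv_kappa,
        test_accuracy = met$accuracy, macro_f = met$macro_f,
        kappa = met$kappa, n_test = met$total, stringsAsFactors = FALSE)
    }
  }
  comp <- do.call(rbind, comp)
  comp <- comp[order(comp$epoch_s, -comp$test_accuracy), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(comparison = comp, results = results),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  df <- x$comparison
  df$test_accuracy <- sprintf("%.1f%%", 100 * df$test_accuracy)
  df$macro_f <- sprintf("%.1f%%", 100 * df$macro_f)
  print(df[c("epoch_s", "model", "test_accuracy", "macro_f", "kappa")],
        row.names = FALSE)
  invisible(x)
}
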