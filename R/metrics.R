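#' Confusion matrix with rows = predicted, columns = observed
#'
#' @param predicted,observed equal-length label vectors.
#' @param classes ordered class labels; defaults to the sorted union.
#' @return a `confusion_matrix`: integer matrix `counts[pred, obs]`.
#' @export
confusion_matrix <- function(predicted, observed, classes = NULL) {
  if (length(predicted) != length(observed))
    stopf("predicted and observed must have equal length")
  predicted <- as.character(predicted)
  observed <- as.character(observed)
  if (is.null(classes)) classes <- sort(unique(c(predicted, observed)))
  bad <- setdiff(unique(c(predicted, observed)), classes)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  m <- table(factor(predicted, levels = classes),
             factor(observed, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(predicted = classes, observed = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Wrap an existing count matrix as a confusion matrix
#'
#' @param counts square non-negative integer matrix, rows = predicted,
#'   columns = observed, with identical row/column names.
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stopf("counts must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (is.null(rownames(counts)) ||
      !identical(rownames(counts), colnames(counts)))
    stopf("rows and columns must carry identical class names")
  names(dimnames(counts)) <- c("predicted", "observed")
  structure(counts, class = c("confusion_matrix", class(counts)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = predicted, columns = observed\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class and overall performance metrics
#'
#' For class i with TP = counts[i,i], FN = column total - TP,
#' FP = row total - TP, TN = the rest:
#' sensitivity = TP/(TP+FN), specificity = TN/(FP+TN),
#' precision = TP/(TP+FP), F = TP/(TP + (FP+FN)/2) (the harmonic mean of
#' precision and sensitivity). Overall: accuracy = trace/total, macro-F =
#' unweighted mean of the defined per-class F values, and Cohen's kappa
#' = (po - pe)/(1 - pe) with pe from the row/column marginals. A class with
#' empty row and column gets `NA` metrics and is excluded from macro-F with
#' a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return a `class_metrics`: list with `per_class` (data.frame of
#'   proportions in [0,1]), `accuracy`, `macro_f`, `kappa`, `total`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  total <- sum(m)
  classes <- rownames(m)
  tp <- diag(m)
  fp <- rowSums(m) - tp
  fn <- colSums(m) - tp
  tn <- total - tp - fp - fn
  empty <- (rowSums(m) + colSums(m)) == 0
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(fp + tn > 0, tn / (fp + tn), NA_real_)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  f <- ifelse(tp + (fp + fn) / 2 > 0, tp / (tp + (fp + fn) / 2), NA_real_)
  sens[empty] <- spec[empty] <- prec[empty] <- f[empty] <- NA_real_
  if (any(empty))
    warnf("class(es) with no observations or predictions excluded from %s",
          paste0("macro-F: ", paste(classes[empty], collapse = ", ")))
  po <- sum(tp) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  structure(list(
    per_class = data.frame(class = classes, sensitivity = sens,
                           specificity = spec, precision = prec,
                           f_measure = f, row.names = NULL,
                           stringsAsFactors = FALSE),
    accuracy = po,
    macro_f = mean(f[!is.na(f)]),
    kappa = kappa,
    total = total), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics> n = %d | accuracy %.1f%% | macro-F %.1f%% | kappa %.3f\n",
              x$total, 100 * x$accuracy, 100 * x$macro_f, x$kappa))
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], function(v) sprintf("%.1f%%", 100 * v))
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Macro-averaged F-measure
#'
#' Unweighted mean of the defined per-class F-measures, giving rare classes
#' equal weight.
#'
#' @param cm a [confusion_matrix()].
#' @return proportion in [0, 1].
#' @export
macro_f <- function(cm) {
  f <- class_metrics(cm)$per_class$f_measure
  if (all(is.na(f))) stopf("no class has a defined F-measure")
  mean(f, na.rm = TRUE)
}

#' Permutation feature importance on a held-out table
#'
#' Model-agnostic importance shared by all eight classifier types: the mean
#' drop in test accuracy over `repeats` independent within-column
#' permutations of each feature.
#'
#' @param fit a fitted model from [tune_and_fit()].
#' @param test_table held-out feature table (66 features + label).
#' @param repeats permutations per feature (default 10).
#' @param seed integer seed.
#' @return data.frame `feature, importance, sd_drop`, sorted by decreasing
#'   importance (mean accuracy drop).
#' @export
permutation_importance <- function(fit, test_table, repeats = 10,
                                   seed = 1L) {
  if (repeats < 1) stopf("repeats must be >= 1")
  feats <- intersect(feature_names(), names(test_table))
  if (length(feats) == 0) stopf("test table carries no known features")
  extra <- setdiff(names(test_table),
                   c(feats, "label", "event_id", "session"))
  feats <- c(feats, extra)  # allow probe columns appended by the caller
  y <- test_table$label
  base <- mean(predict_model(fit, test_table) == y)
  set.seed(derive_seed(seed, 3))
  drops <- matrix(NA_real_, repeats, length(feats),
                  dimnames = list(NULL, feats))
  for (f in feats) {
    for (r in seq_len(repeats)) {
      perm <- test_table
      perm[[f]] <- perm[[f]][sample.int(nrow(perm))]
      drops[r, f] <- base - mean(predict_model(fit, perm) == y)
    }
  }
  out <- data.frame(feature = feats, importance = colMeans(drops),
                    sd_drop = apply(drops, 2, stats::sd), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}
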