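#' Reference test-set confusion matrices
#'
#' The package bundles the test-set confusion-matrix counts reported by a
#' captive Port Jackson shark study for its three best classifiers (SVM,
#' RF, XGB) at 1 s and 2 s epochs — 82 test epochs per matrix. They anchor
#' the evaluation layer: recomputing the metric set from these counts must
#' reproduce the study's printed percentages. As printed, the matrices are
#' consistent with rows = predicted and columns = observed (the printed
#' sensitivities equal TP over column totals, the precisions TP over row
#' totals), and they are stored under that reading.
#'
#' @return named list of [confusion_matrix()] objects, names like
#'   `"SVM_2s"`.
#' @export
reference_confusion_matrices <- function() {
  path <- system.file("extdata", "reference_confusion_counts.csv",
                      package = "behavacc", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  classes <- c("chew", "rest", "swim", "vertical_swim")
  out <- list()
  for (key in unique(paste(raw$model, raw$epoch_s))) {
    sub <- raw[paste(raw$model, raw$epoch_s) == key, ]
    m <- as.matrix(sub[classes])
    rownames(m) <- sub$predicted
    m <- m[classes, ]
    colnames(m) <- classes
    out[[sprintf("%s_%ss", sub$model[1], sub$epoch_s[1])]] <-
      as_confusion_matrix(m)
  }
  out
}

#' Metric values as printed alongside the reference matrices
#'
#' Per-class sensitivity/specificity/precision/F and overall
#' accuracy/macro-F as the source study printed them (percent, mixed
#' precision: some cells to one decimal, some whole). Values are returned
#' as character strings so the printed precision of each cell is
#' recoverable (e.g. `"77"` means a half-point rounding band, `"76.9"` a
#' 0.05 band).
#'
#' @return list with data.frames `per_class` and `overall`.
#' @export
reference_reported_metrics <- function() {
  pc <- utils::read.csv(system.file("extdata",
                                    "reference_reported_metrics.csv",
                                    package = "behavacc", mustWork = TRUE),
                        colClasses = "character")
  ov <- utils::read.csv(system.file("extdata",
                                    "reference_reported_overall.csv",
                                    package = "behavacc", mustWork = TRUE),
                        colClasses = "character")
  list(per_class = pc, overall = ov)
}

#' Half-width of the rounding band implied by a printed number
#'
#' @param printed character vector of numbers as printed (e.g. `"68.4"`,
#'   `"77"`, `"100"`).
#' @return numeric vector: 0.5 * 10^-decimals.
#' @export
printed_tolerance <- function(printed) {
  dec <- ifelse(grepl("\\.", printed),
                nchar(sub("^[^.]*\\.", "", printed)), 0L)
  0.5 * 10^(-dec)
}

#' Does a computed value reproduce a printed one?
#'
#' A computed value counts as reproducing a printed cell when it rounds
#' (half up) to the printed number at the printed precision, either
#' directly or after first rounding to one extra decimal — the bundled
#' tables were evidently double-rounded in one cell (93.548 printed as
#' 93.6 via 93.55).
#'
#' @param computed numeric vector.
#' @param printed character vector of numbers as printed.
#' @return logical vector.
#' @export
matches_printed <- function(computed, printed) {
  dec <- ifelse(grepl("\\.", printed),
                nchar(sub("^[^.]*\\.", "", printed)), 0L)
  half_up <- function(v, d) floor(v * 10^d + 0.5 + 1e-9) / 10^d
  p <- as.numeric(printed)
  direct <- abs(half_up(computed, dec) - p) < 1e-9
  double <- abs(half_up(half_up(computed, dec + 1L), dec) - p) < 1e-9
  direct | double
}

#' Recompute every reference metric cell from the bundled counts
#'
#' Feeds each bundled confusion matrix through [class_metrics()] and pairs
#' every computed percentage with the printed value and its rounding band.
#'
#' @return data.frame with columns `model, epoch_s, class, metric,
#'   computed` (percent), `reported` (printed string), `tolerance`,
#'   `within` (logical); overall accuracy and macro-F rows carry class
#'   `"overall"`.
#' @export
reproduce_reference_metrics <- function() {
  cms <- reference_confusion_matrices()
  rep <- reference_reported_metrics()
  rows <- list()
  for (key in names(cms)) {
    model <- sub("_[12]s$", "", key)
    ep <- sub("s$", "", sub("^.*_", "", key))
    met <- class_metrics(cms[[key]])
    pc <- rep$per_class[rep$per_class$model == model &
                          rep$per_class$epoch_s == ep, ]
    for (metric in c("sensitivity", "specificity", "precision",
                     "f_measure")) {
      comp <- 100 * met$per_class[[metric]][
        match(pc$class, met$per_class$class)]
      rows[[length(rows) + 1]] <- data.frame(
        model = model, epoch_s = as.numeric(ep), class = pc$class,
        metric = metric, computed = comp, reported = pc[[metric]],
        stringsAsFactors = FALSE)
    }
    ov <- rep$overall[rep$overall$model == model &
                        rep$overall$epoch_s == ep, ]
    rows[[length(rows) + 1]] <- data.frame(
      model = model, epoch_s = as.numeric(ep), class = "overall",
      metric = c("accuracy", "macro_f"),
      computed = 100 * c(met$accuracy, met$macro_f),
      reported = c(ov$accuracy, ov$macro_f), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$tolerance <- printed_tolerance(out$reported)
  out$within <- matches_printed(out$computed, out$reported)
  rownames(out) <- NULL
  out
}
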