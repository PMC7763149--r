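MERGE_FEATURES <- c("odba_mean", "odba_sd", "vedba_sd", "vedba_max")

#' Test whether the two swimming classes merge
#'
#' Water-column and floor swimming share biomechanics; they are compared on
#' four epoch summary features (mean and SD of ODBA, SD and maximum of
#' VeDBA) with Welch two-sample t-tests. The two classes are combined into a
#' single `swim` class only when *none* of the four features differs
#' significantly (all p >= alpha); no multiple-testing correction is applied
#' across the four comparisons.
#'
#' @param feature_table epoch feature table from [build_feature_table()].
#' @param alpha significance level (default 0.05).
#' @return a `merge_report`: list with `tests` (data.frame of t, df, p per
#'   feature), `decision` ("merge" or "keep_separate"), `alpha`, and
#'   `missing_class` flag.
#' @export
compare_swim_classes <- function(feature_table, alpha = 0.05) {
  a <- feature_table[feature_table$label == "swim_column", , drop = FALSE]
  b <- feature_table[feature_table$label == "swim_floor", , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    rep <- structure(list(tests = NULL, decision = "keep_separate",
                          alpha = alpha, missing_class = TRUE),
                     class = "merge_report")
    return(rep)
  }
  tests <- do.call(rbind, lapply(MERGE_FEATURES, function(f) {
    tt <- welch_t(a[[f]], b[[f]])
    data.frame(feature = f, t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  }))
  decision <- if (all(tests$p >= alpha)) "merge" else "keep_separate"
  structure(list(tests = tests, decision = decision, alpha = alpha,
                 missing_class = FALSE), class = "merge_report")
}

# Welch t-test guarding the degenerate case of two constant groups, where
# stats::t.test() refuses: equal constants give t = 0, p = 1, differing
# constants t = +/-Inf, p = 0.
welch_t <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(x) + length(y) - 2,
                p = if (d == 0) 1 else 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("<merge_report> decision:", x$decision,
      sprintf("(alpha = %g)\n", x$alpha))
  if (isTRUE(x$missing_class))
    cat("  one or both swim classes absent from the table\n")
  if (!is.null(x$tests)) print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Apply the ethogram rules to a feature table
#'
#' Drops `other` and `out_of_camera` epochs and, when the merge report says
#' so, relabels `swim_column` and `swim_floor` as `swim`. Feature values are
#' never modified, only labels and row membership.
#'
#' @param feature_table epoch feature table with raw labels.
#' @param merge_report result of [compare_swim_classes()], or the strings
#'   `"always"`/`"never"` to force the decision.
#' @return the modelling table with labels in
#'   {rest, swim, vertical_swim, chew} (swim split in two if kept separate).
#' @export
apply_ethogram <- function(feature_table, merge_report) {
  out <- feature_table[!(feature_table$label %in% EXCLUDED_LABELS), ,
                       drop = FALSE]
  decision <- if (is.character(merge_report)) {
    switch(merge_report, always = "merge", never = "keep_separate",
           stopf("merge_report must be 'always', 'never' or a merge_report"))
  } else merge_report$decision
  if (decision == "merge")
    out$label[out$label %in% c("swim_column", "swim_floor")] <- "swim"
  if (nrow(out) == 0) stopf("no epochs left after ethogram filtering")
  rownames(out) <- NULL
  out
}
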