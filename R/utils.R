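#' @keywords internal
"_PACKAGE"

# Raw labels the generator and ethogram know about. `other` and
# `out_of_camera` are coded during observation but never modelled.
RAW_LABELS <- c("rest", "swim_column", "swim_floor", "swim",
                "vertical_swim", "chew", "other", "out_of_camera")
EXCLUDED_LABELS <- c("other", "out_of_camera")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; each stage or
#' session gets its own stream via a fixed integer hash so that stages can be
#' re-run in isolation without replaying the whole pipeline.
#'
#' @param master integer master seed.
#' @param stage integer stage/session index (>= 0).
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, stage) {
  master <- as.double(master) %% 2147483647
  ((master * 7919 + as.double(stage) * 104729) %% 2147483629) + 1
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == round(x)
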