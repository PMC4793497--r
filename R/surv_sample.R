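#' Construct a censored survival sample
#'
#' A `surv_sample` holds one group's right-censored observations: the observed
#' time \eqn{Z = \min(X, Y)} and the event indicator
#' \eqn{\delta = I(X \le Y)}, where \eqn{X} is the survival time and \eqn{Y}
#' the censoring time.  \eqn{\delta = 1} means the event was observed,
#' \eqn{\delta = 0} means the observation was censored.
#'
#' Times may be any finite reals: shifted survival families (e.g. an
#' exponential shifted by a location constant) legitimately produce times far
#' from zero, so no positivity is required.
#'
#' @param times numeric vector of observed times \eqn{Z}.
#' @param events vector of event indicators, each 0/1 (logical accepted).
#' @param label optional group identifier (any scalar).
#' @return An object of class `surv_sample`: a list with elements `times`,
#'   `events` (integer 0/1) and `label`.
#' @examples
#' surv_sample(c(5, 8, 12, 20), c(1, 1, 0, 1), label = "treated")
#' @export
surv_sample <- function(times, events, label = NULL) {
  times <- as.numeric(times)
  if (is.logical(events)) events <- as.integer(events)
  events <- as.integer(events)
  if (length(times) == 0L) {
    stop_invalid_input("a survival sample must contain at least one observation")
  }
  if (length(times) != length(events)) {
    stop_invalid_input(sprintf(
      "times (%d) and events (%d) must have equal length",
      length(times), length(events)))
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop_invalid_input("all observed times must be finite and non-missing")
  }
  if (anyNA(events) || !all(events %in% c(0L, 1L))) {
    stop_invalid_input("every event indicator must be 0 (censored) or 1 (event)")
  }
  structure(list(times = times, events = events, label = label),
            class = "surv_sample")
}

#' @export
print.surv_sample <- function(x, ...) {
  cat(sprintf("Censored survival sample%s: n = %d, events = %d, censored = %d\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$times), sum(x$events), sum(1L - x$events)))
  invisible(x)
}

#' Bundle K survival samples for a K-group comparison
#'
#' @param samples a list of [surv_sample()] objects, one per group, in the
#'   order groups should be reported.  At least two groups are required.
#' @return An object of class `grouped_surv`: a list of `surv_sample`s.
#' @examples
#' g1 <- surv_sample(1:4, rep(1, 4), "A")
#' g2 <- surv_sample(2:5, rep(1, 4), "B")
#' grouped_surv(list(g1, g2))
#' @export
grouped_surv <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop_invalid_input("need K >= 2 groups to compare medians")
  }
  ok <- vapply(samples, inherits, logical(1), what = "surv_sample")
  if (!all(ok)) {
    stop_invalid_input("every element of 'samples' must be a surv_sample")
  }
  labels <- vapply(seq_along(samples), function(i) {
    lb <- samples[[i]]$label
    if (is.null(lb)) as.character(i) else as.character(lb)
  }, character(1))
  names(samples) <- labels
  structure(samples, class = "grouped_surv")
}

#' Build grouped survival data from a long-format data frame
#'
#' @param data a data.frame with one row per subject.
#' @param time,event,group column names holding the observed time, the 0/1
#'   event indicator, and the group label.
#' @return A [grouped_surv()] object with groups in their order of first
#'   appearance in `data`.
#' @export
as_grouped_surv <- function(data, time = "time", event = "event",
                            group = "group") {
  for (col in c(time, event, group)) {
    if (!col %in% names(data)) {
      stop_invalid_input(sprintf("column '%s' not found in input", col))
    }
  }
  gvals <- data[[group]]
  levels_seen <- unique(gvals)
  samples <- lapply(levels_seen, function(g) {
    idx <- which(gvals == g)
    surv_sample(data[[time]][idx], data[[event]][idx], label = g)
  })
  grouped_surv(samples)
}

#' @export
print.grouped_surv <- function(x, ...) {
  cat(sprintf("Grouped survival data: K = %d groups\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

# typed error helpers ---------------------------------------------------

stop_invalid_input <- function(msg) {
  stop(errorCondition(msg, class = c("survmedian_invalid_input",
                                     "survmedian_error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("survmedian_degenerate",
                                     "survmedian_error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("survmedian_config",
                                     "survmedian_error")))
}
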