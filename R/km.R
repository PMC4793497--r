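#' Kaplan-Meier product-limit curve
#'
#' Fits the product-limit estimator of the survival function
#' \eqn{\hat F(t) = \prod_{t_j \le t} (1 - d_j / n_j)} over the distinct
#' event times \eqn{t_j}, where \eqn{d_j} is the number of events at
#' \eqn{t_j} and \eqn{n_j} the number at risk (observations with
#' \eqn{Z \ge t_j}).  Subjects censored at \eqn{t_j} remain in the risk set
#' for events at \eqn{t_j} (events precede censorings at tied times).  The
#' curve is right-continuous: evaluation at an event time includes that
#' event's jump.
#'
#' Alongside the curve the cumulative Greenwood terms
#' \eqn{\sum_{t_j \le t} d_j / (n_j (n_j - d_j))} are accumulated, so the
#' Greenwood variance of \eqn{\hat F(t)} is available at any time point.
#'
#' @param sample a [surv_sample()].
#' @return An object of class `km_curve` with elements `event_times`
#'   (strictly increasing distinct times with at least one event),
#'   `surv` (\eqn{\hat F} just after each event time), `n_risk`, `n_event`,
#'   `greenwood_cum`, and `n` (sample size).  With no observed events the
#'   curve is identically 1 and all event-level vectors are empty.
#' @seealso [km_survival_at()], [km_median()], [greenwood_variance_at()]
#' @examples
#' km_fit(surv_sample(c(1, 2, 3, 4), c(1, 1, 1, 1)))
#' @export
km_fit <- function(sample) {
  if (!inherits(sample, "surv_sample")) sample <- surv_sample(sample$times, sample$events)
  km_compute(sample$times, sample$events)
}

# core product-limit computation on bare vectors; hot path for the
# simulation engine, so no S3 validation here
km_compute <- function(times, events) {
  n <- length(times)
  ev_times <- times[events == 1L]
  if (length(ev_times) == 0L) {
    return(structure(list(event_times = numeric(0), surv = numeric(0),
                          n_risk = integer(0), n_event = integer(0),
                          greenwood_cum = numeric(0), n = n),
                     class = "km_curve"))
  }
  ut <- sort(unique(ev_times))
  st <- sort(times)
  # at risk at t_j: observations with Z >= t_j
  n_risk <- n - findInterval(ut, st, left.open = TRUE)
  n_event <- tabulate(match(ev_times, ut), nbins = length(ut))
  surv <- cumprod(1 - n_event / n_risk)
  term <- n_event / (n_risk * (n_risk - n_event))
  term[n_event == n_risk] <- 0  # survival hits 0; F^2 factor annihilates
  structure(list(event_times = ut, surv = surv,
                 n_risk = as.integer(n_risk), n_event = as.integer(n_event),
                 greenwood_cum = cumsum(term), n = n),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d distinct event times\n",
              x$n, length(x$event_times)))
  if (length(x$event_times)) {
    print(data.frame(time = x$event_times, n_risk = x$n_risk,
                     n_event = x$n_event, surv = x$surv),
          row.names = FALSE)
  } else {
    cat("no events observed; curve is identically 1\n")
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous evaluation: \eqn{\hat F(t)} is 1 before the first event
#' time, and otherwise the survival probability at the largest event time
#' \eqn{\le t}.
#'
#' @param curve a [km_fit()] result.
#' @param t numeric vector of time points (finite).
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  j <- findInterval(t, curve$event_times)
  out <- rep(1, length(t))
  hit <- j > 0L
  out[hit] <- curve$surv[j[hit]]
  out
}

#' Greenwood variance of the Kaplan-Meier estimate at a time point
#'
#' Computes \eqn{\hat F(t)^2 \sum_{t_j \le t} d_j / (n_j (n_j - d_j))}, the
#' classical Greenwood variance estimate of the product-limit survival
#' probability.  It is 0 before the first event time, and 0 wherever the
#' estimated survival has reached 0 (the \eqn{\hat F^2} factor annihilates
#' the sum; the undefined \eqn{1/(n_j - d_j)} term at a total-failure time is
#' skipped).
#'
#' @inheritParams km_survival_at
#' @return numeric vector of variances.
#' @export
greenwood_variance_at <- function(curve, t) {
  j <- findInterval(t, curve$event_times)
  out <- numeric(length(t))
  hit <- j > 0L
  out[hit] <- curve$surv[j[hit]]^2 * curve$greenwood_cum[j[hit]]
  out
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The median is \eqn{\hat\theta = \inf\{t : \hat F(t) \le 0.5\}}, the
#' smallest event time at which the estimated survival drops to one half or
#' below.  When the curve never reaches 0.5 (e.g. heavy censoring) the median
#' is undefined and `NA` is returned; callers must treat that as a reportable
#' condition, not a value.
#'
#' @param curve a [km_fit()] result.
#' @return the median survival time, or `NA_real_` when undefined.
#' @export
km_median <- function(curve) {
  idx <- which(curve$surv <= 0.5)
  if (length(idx) == 0L) return(NA_real_)
  curve$event_times[idx[1L]]
}

#' Closest uncensored time to a reference time
#'
#' Among the distinct uncensored (event) times of a sample, excluding any
#' time exactly equal to `ref`, returns the one minimizing the absolute
#' distance to `ref`.  An exact distance tie is broken toward the smaller
#' time.  Used by the composite variance estimate, where the group median
#' (itself typically an uncensored time) serves as the reference and the
#' neighbouring event time quantifies the local variability of the median.
#'
#' @param sample a [surv_sample()].
#' @param ref finite reference time.
#' @return the closest distinct uncensored time, or `NA_real_` when no
#'   uncensored time other than `ref` exists.
#' @export
closest_uncensored_time <- function(sample, ref) {
  u <- unique(sample$times[sample$events == 1L])
  u <- u[u != ref]
  if (length(u) == 0L) return(NA_real_)
  d <- abs(u - ref)
  u[order(d, u)][1L]
}
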