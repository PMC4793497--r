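#' Specify one group's survival and censoring distributions
#'
#' The simulation engine draws survival times from one of three families,
#' each shifted/scaled by a location parameter `theta` and a scale parameter
#' `a` (plus a divisor `c` for the uniform family):
#' \describe{
#'   \item{uniform}{\eqn{U(-a/c, a/c) + \theta}; median \eqn{\theta}.}
#'   \item{exponential}{\eqn{\theta + Exp(rate = a)}; median
#'     \eqn{\theta + \log(2)/a}.}
#'   \item{lognormal}{\eqn{\exp(\theta + a Z)} with \eqn{Z} standard normal
#'     (log-location \eqn{\theta}, log-scale \eqn{a}); median
#'     \eqn{e^\theta}.}
#' }
#' Each family has a matched censoring-time family (see
#' [sample_censoring()]) parameterized by the target censoring rate `p`.
#'
#' @param family `"uniform"`, `"exponential"` or `"lognormal"`.
#' @param theta location (uniform/exponential) or log-location (lognormal).
#' @param a half-width numerator (uniform), rate (exponential) or log-scale
#'   (lognormal); must be positive.
#' @param c uniform-family divisor (support half-width is `a/c`); ignored by
#'   the other families.
#' @param n group sample size (at least 2).
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(family, theta, a, c = NA_real_, n) {
  family <- match.arg(family, c("uniform", "exponential", "lognormal"))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop_config("'a' must be a single positive number")
  }
  if (family == "uniform" && (!is.finite(c) || c <= 0)) {
    stop_config("the uniform family requires a positive divisor 'c'")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop_config("group sample size 'n' must be at least 2")
  }
  structure(list(family = family, theta = as.numeric(theta),
                 a = as.numeric(a), c = as.numeric(c), n = as.integer(n)),
            class = "group_spec")
}

#' Draw survival times for one group
#'
#' Draws `spec$n` survival times from the group's family using the current
#' RNG state.
#'
#' @param spec a [group_spec()].
#' @return numeric vector of length `spec$n`.
#' @export
sample_survival <- function(spec) {
  n <- spec$n
  switch(spec$family,
    uniform = stats::runif(n, spec$theta - spec$a / spec$c,
                              spec$theta + spec$a / spec$c),
    exponential = spec$theta + stats::rexp(n, rate = spec$a),
    lognormal = exp(spec$theta + spec$a * stats::rnorm(n)),
    stop_config(sprintf("unknown survival family '%s'", spec$family)))
}

#' Draw censoring times for one group
#'
#' The censoring family is matched to the survival family and parameterized
#' by the target censoring rate `p`:
#' \describe{
#'   \item{uniform}{\eqn{U(-a/c,\; a/c + (1-2p)/p) + \theta}.}
#'   \item{exponential}{\eqn{\theta + Exp(rate = a p/(1-p))}; by the
#'     competing-exponentials identity the realized censoring probability is
#'     exactly \eqn{p}.}
#'   \item{lognormal}{log-uniform \eqn{\exp(\theta + a\,U(-2, -2 + 2/p))};
#'     for small \eqn{p} the probability that the log-uniform draw falls
#'     below a standard normal is approximately \eqn{p}.}
#' }
#' With `p = 0` all censoring times are `+Inf` (no observation censored).
#' For the uniform family the realized rate equals `p` only when the support
#' half-width `a/c` is 1 (it is `w/(2w + (1-2p)/p)` with `w = a/c` in
#' general); scenarios are run with their printed parameters, not re-tuned.
#'
#' @param spec a [group_spec()].
#' @param p target censoring rate in \[0, 1).
#' @return numeric vector of length `spec$n` (possibly `Inf`).
#' @export
sample_censoring <- function(spec, p) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1) {
    stop_config("censoring rate 'p' must lie in [0, 1)")
  }
  n <- spec$n
  if (p == 0) return(rep(Inf, n))
  switch(spec$family,
    uniform = stats::runif(n, spec$theta - spec$a / spec$c,
                              spec$theta + spec$a / spec$c + (1 - 2 * p) / p),
    exponential = spec$theta + stats::rexp(n, rate = spec$a * p / (1 - p)),
    lognormal = exp(spec$theta + spec$a * stats::runif(n, -2, -2 + 2 / p)),
    stop_config(sprintf("unknown survival family '%s'", spec$family)))
}

#' Specify one simulation scenario
#'
#' A scenario is one cell of the Monte-Carlo study: K group specifications,
#' a common target censoring rate, a significance level, a replicate count
#' and an RNG seed.
#'
#' @param groups list of [group_spec()] objects (K of them, K >= 2).
#' @param censor_rate target censoring rate p in \[0, 1).
#' @param alpha significance level in (0, 1).
#' @param reps number of Monte-Carlo replicates.
#' @param seed integer RNG seed for the scenario.
#' @param label free-form scenario identifier used in reports.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(groups, censor_rate, alpha = 0.05,
                          reps = 10000L, seed = 1L, label = NULL) {
  if (!is.list(groups) || length(groups) < 2L ||
      !all(vapply(groups, inherits, logical(1), "group_spec"))) {
    stop_config("'groups' must be a list of at least two group_spec objects")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop_config("censoring rate must lie in [0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  if (reps < 1) stop_config("reps must be at least 1")
  structure(list(groups = groups, censor_rate = as.numeric(censor_rate),
                 alpha = as.numeric(alpha), reps = as.integer(reps),
                 seed = as.integer(seed),
                 label = if (is.null(label)) "scenario" else as.character(label)),
            class = "scenario_spec")
}

#' Generate one replicate of grouped censored data from a scenario
#'
#' For each group, survival times X and censoring times Y are drawn
#' independently from the group's families and paired into the observed data
#' \eqn{Z = \min(X, Y)}, \eqn{\delta = I(X \le Y)}.
#'
#' @param spec a [scenario_spec()].
#' @return a [grouped_surv()] object with one sample per group.
#' @export
generate_grouped_data <- function(spec) {
  raw <- generate_raw(spec)
  grouped_surv(lapply(seq_along(raw), function(i) {
    surv_sample(raw[[i]]$times, raw[[i]]$events, label = i)
  }))
}

# bare-vector replicate generator used by the hot loop
generate_raw <- function(spec) {
  lapply(spec$groups, function(g) {
    x <- sample_survival(g)
    y <- sample_censoring(g, spec$censor_rate)
    list(times = pmin(x, y), events = as.integer(x <= y))
  })
}
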