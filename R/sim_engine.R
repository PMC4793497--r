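# --- scenario catalog -------------------------------------------------
#
# Six tables of K = 4 scenarios.  Tables 1-3 use the large sample-size set
# (100, 150, 150, 200); tables 4-6 the small set (20, 25, 25, 30).
# Tables 1/4: null, identical distributions.  Tables 2/5: null, equal
# medians with unequal variances (including mixed-family rows).
# Tables 3/6: unequal medians (power).  Row parameters are vectors over
# the four groups; mixed rows assign families in the order named by the
# row key (e.g. uniform_exponential = two uniform then two exponential).

.rows_null_same <- list(
  uniform = list(family = rep("uniform", 4), theta = rep(10, 4),
                 a = rep(4, 4), c = rep(2, 4)),
  exponential = list(family = rep("exponential", 4), theta = rep(10, 4),
                     a = rep(0.1, 4), c = rep(NA_real_, 4)),
  lognormal = list(family = rep("lognormal", 4), theta = rep(log(10), 4),
                   a = rep(0.3, 4), c = rep(NA_real_, 4))
)

.rows_null_hetero <- list(
  uniform = list(family = rep("uniform", 4), theta = rep(10, 4),
                 a = rep(4, 4), c = c(2, 3, 4, 5)),
  exponential = list(family = rep("exponential", 4),
                     theta = 10 - c(2, 3, 4, 5) * log(2),
                     a = 1 / c(2, 3, 4, 5), c = rep(NA_real_, 4)),
  lognormal = list(family = rep("lognormal", 4), theta = rep(log(10), 4),
                   a = c(0.2, 0.3, 0.4, 0.5), c = rep(NA_real_, 4)),
  uniform_exponential = list(
    family = c("uniform", "uniform", "exponential", "exponential"),
    theta = c(10, 10, 10 - 10 * log(2), 10 - 10 * log(2)),
    a = rep(0.1, 4), c = rep(0.01, 4)),
  uniform_lognormal = list(
    family = c("uniform", "uniform", "lognormal", "lognormal"),
    theta = c(10, 10, log(10), log(10)),
    a = c(5, 5, 0.3, 0.3), c = rep(2, 4)),
  lognormal_exponential = list(
    family = c("lognormal", "lognormal", "exponential", "exponential"),
    theta = c(log(10), log(10), 10 - log(2) / 0.3, 10 - log(2) / 0.3),
    a = rep(0.3, 4), c = rep(NA_real_, 4))
)

.rows_power <- list(
  uniform = list(family = rep("uniform", 4), theta = c(10, 10, 10.5, 10),
                 a = rep(4, 4), c = rep(2, 4)),
  exponential = list(family = rep("exponential", 4), theta = rep(10, 4),
                     a = c(0.1, 0.15, 0.15, 0.1), c = rep(NA_real_, 4)),
  lognormal = list(family = rep("lognormal", 4),
                   theta = log(c(10, 14, 14, 10)),
                   a = rep(1, 4), c = rep(NA_real_, 4)),
  uniform_exponential = list(
    family = c("uniform", "uniform", "exponential", "exponential"),
    theta = c(10, 13, 13 - 10 * log(2), 10 - 10 * log(2)),
    a = rep(0.1, 4), c = rep(0.01, 4)),
  uniform_lognormal = list(
    family = c("uniform", "uniform", "lognormal", "lognormal"),
    theta = c(10, 12, 2.5, 2.5),
    a = rep(1, 4), c = rep(0.2, 4)),
  lognormal_exponential = list(
    family = c("lognormal", "lognormal", "exponential", "exponential"),
    theta = c(log(10), log(13), 13 - 10 * log(2), 10 - 10 * log(2)),
    a = c(1, 1, 0.1, 0.1), c = rep(NA_real_, 4))
)

.catalog_tables <- list(
  `1` = list(rows = .rows_null_same,   n = c(100, 150, 150, 200)),
  `2` = list(rows = .rows_null_hetero, n = c(100, 150, 150, 200)),
  `3` = list(rows = .rows_power,       n = c(100, 150, 150, 200)),
  `4` = list(rows = .rows_null_same,   n = c(20, 25, 25, 30)),
  `5` = list(rows = .rows_null_hetero, n = c(20, 25, 25, 30)),
  `6` = list(rows = .rows_power,       n = c(20, 25, 25, 30))
)

.catalog_rates <- c(0, 0.1, 0.2, 0.3)

#' Look up a Monte-Carlo scenario from the built-in catalog
#'
#' The catalog enumerates the simulation study's six tables of four-group
#' scenarios.  Tables 1-3 use sample sizes (100, 150, 150, 200); tables 4-6
#' use (20, 25, 25, 30).  Tables 1 and 4 hold the null scenarios with
#' identical group distributions (rows `uniform`, `exponential`,
#' `lognormal`); tables 2 and 5 the null scenarios with equal medians but
#' unequal variances, including mixed-family rows; tables 3 and 6 the
#' unequal-median (power) scenarios.  Valid row keys per table are listed by
#' [scenario_rows()].
#'
#' @param table table number, 1 through 6.
#' @param row row key, e.g. `"uniform"` or `"uniform_exponential"`.
#' @param censor_rate one of 0, 0.1, 0.2, 0.3.
#' @param alpha significance level (default 0.05, as in the study).
#' @param reps number of replicates (default 10000, as in the study).
#' @param seed scenario RNG seed.
#' @return a fully populated [scenario_spec()].
#' @examples
#' scenario_catalog(1, "uniform", 0)
#' @export
scenario_catalog <- function(table, row, censor_rate, alpha = 0.05,
                             reps = 10000L, seed = 1L) {
  tkey <- as.character(table)
  if (!tkey %in% names(.catalog_tables)) {
    stop_config(sprintf("unknown table '%s'; valid tables: %s",
                        tkey, paste(names(.catalog_tables), collapse = ", ")))
  }
  tab <- .catalog_tables[[tkey]]
  if (!row %in% names(tab$rows)) {
    stop_config(sprintf("unknown row '%s' for table %s; valid rows: %s",
                        row, tkey, paste(names(tab$rows), collapse = ", ")))
  }
  if (!any(abs(censor_rate - .catalog_rates) < 1e-12)) {
    stop_config(sprintf("censoring rate %s not in the catalog; valid rates: %s",
                        format(censor_rate),
                        paste(.catalog_rates, collapse = ", ")))
  }
  r <- tab$rows[[row]]
  groups <- lapply(seq_len(4), function(i) {
    group_spec(r$family[i], r$theta[i], r$a[i], r$c[i], tab$n[i])
  })
  scenario_spec(groups, censor_rate = censor_rate, alpha = alpha,
                reps = reps, seed = seed,
                label = sprintf("table%s:%s:p%s", tkey, row,
                                format(censor_rate)))
}

#' List the valid row keys of a catalog table
#'
#' @param table table number, 1 through 6.
#' @return character vector of row keys.
#' @export
scenario_rows <- function(table) {
  tkey <- as.character(table)
  if (!tkey %in% names(.catalog_tables)) {
    stop_config(sprintf("unknown table '%s'; valid tables: %s",
                        tkey, paste(names(.catalog_tables), collapse = ", ")))
  }
  names(.catalog_tables[[tkey]]$rows)
}

#' Catalog censoring rates
#' @return the censoring rates available in the scenario catalog.
#' @export
scenario_rates <- function() .catalog_rates

# --- test evaluation hot path -----------------------------------------

# p-values of both variants for one replicate of bare (times, events)
# lists; returns NA for a variant whose variance estimate degenerates,
# NULL when the pooled median itself is undefined
replicate_pvalues <- function(raw) {
  times <- unlist(lapply(raw, `[[`, "times"), use.names = FALSE)
  events <- unlist(lapply(raw, `[[`, "events"), use.names = FALSE)
  theta0 <- km_median(km_compute(times, events))
  if (is.na(theta0)) return(NULL)
  K <- length(raw)
  etas <- gw <- corr <- numeric(K)
  for (i in seq_len(K)) {
    vc <- variance_components(raw[[i]]$times, raw[[i]]$events, theta0)
    etas[i] <- vc$eta; gw[i] <- vc$greenwood; corr[i] <- vc$correction
  }
  df <- K - 1L
  comp_var <- gw + corr
  p_comp <- if (any(comp_var <= 0)) NA_real_ else
    stats::pchisq(cochran_stat(etas, comp_var), df, lower.tail = FALSE)
  p_gw <- if (any(gw <= 0)) NA_real_ else
    stats::pchisq(cochran_stat(etas, gw), df, lower.tail = FALSE)
  c(composite = p_comp, greenwood = p_gw)
}

# --- the Monte-Carlo driver -------------------------------------------

#' Run the Monte-Carlo study for one scenario
#'
#' Draws `spec$reps` replicates of grouped censored data, applies the
#' requested test variants to each, and reports the empirical rejection
#' proportion at level `spec$alpha` per variant together with its
#' Monte-Carlo standard error \eqn{\sqrt{r(1-r)/reps}}.
#'
#' Each replicate is generated on its own L'Ecuyer-CMRG RNG stream spawned
#' from the scenario seed, so results are reproducible and independent of
#' evaluation order.  A replicate on which any requested variant is
#' degenerate (undefined pooled median, or a zero variance estimate in some
#' group) is discarded and redrawn on a fresh stream; the number of such
#' redraws is reported as `degenerate_count`.  Degeneracy is rare at the
#' catalog's censoring rates (at most 30\%); if redraws ever exceed the
#' replicate count the scenario is declared ill-posed and the run aborts.
#'
#' @param spec a [scenario_spec()] (e.g. from [scenario_catalog()]).
#' @param variants which test variants to evaluate; subset of
#'   `c("composite", "greenwood")`.
#' @return an object of class `sim_result`: rejection proportions and MC
#'   standard errors per variant, the replicate p-values, the degenerate
#'   redraw count, and the scenario.
#' @examples
#' sc <- scenario_catalog(4, "exponential", 0.1, reps = 50, seed = 7)
#' run_simulation(sc)
#' @export
run_simulation <- function(spec, variants = c("composite", "greenwood")) {
  variants <- match.arg(variants, several.ok = TRUE)
  reps <- spec$reps
  pmat <- matrix(NA_real_, nrow = reps, ncol = 2,
                 dimnames = list(NULL, c("composite", "greenwood")))
  degenerate <- 0L
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv())
  for (r in seq_len(reps)) {
    repeat {
      assign(".Random.seed", stream, envir = globalenv())
      stream <- parallel::nextRNGStream(stream)
      pv <- replicate_pvalues(generate_raw(spec))
      ok <- !is.null(pv) && !anyNA(pv[variants])
      if (ok) { pmat[r, ] <- pv; break }
      degenerate <- degenerate + 1L
      if (degenerate > reps) {
        stop_degenerate(sprintf(
          "scenario '%s' is ill-posed: more degenerate replicates (%d) than requested replicates (%d)",
          spec$label, degenerate, reps))
      }
    }
  }
  rej <- colMeans(pmat[, variants, drop = FALSE] <= spec$alpha)
  structure(list(
    rejection = rej,
    mc_se = sqrt(rej * (1 - rej) / reps),
    reps = reps,
    degenerate_count = degenerate,
    alpha = spec$alpha,
    p_values = pmat[, variants, drop = FALSE],
    spec = spec
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo result for scenario '%s'\n", x$spec$label))
  cat(sprintf("replicates: %d (degenerate redraws: %d), alpha = %s\n",
              x$reps, x$degenerate_count, format(x$alpha)))
  print(data.frame(variant = names(x$rejection),
                   rejection = round(x$rejection, 4),
                   mc_se = round(x$mc_se, 4)),
        row.names = FALSE)
  invisible(x)
}

#' One-row-per-variant summary of a simulation result
#'
#' @param x a `sim_result`.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return a data.frame with columns label, variant, rejection, mc_se,
#'   reps, degenerate_count, alpha, censor_rate, seed.
#' @export
as.data.frame.sim_result <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(label = x$spec$label,
             variant = names(x$rejection),
             rejection = unname(x$rejection),
             mc_se = unname(x$mc_se),
             reps = x$reps,
             degenerate_count = x$degenerate_count,
             alpha = x$alpha,
             censor_rate = x$spec$censor_rate,
             seed = x$spec$seed,
             row.names = row.names,
             stringsAsFactors = FALSE)
}
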