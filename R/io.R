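#' Read a delimited survival table into grouped survival data
#'
#' Reads a delimited text file with one row per subject and (at least) three
#' columns: the observed time, the event indicator and the group label.  The
#' event indicator convention is \eqn{\delta = 1} for an observed event and
#' \eqn{\delta = 0} for a censored observation (logical `TRUE`/`FALSE` is
#' also accepted).  Other encodings (e.g. `"dead"`/`"alive"`) are off by
#' default and must be declared explicitly via `aliases`.
#'
#' @param path path to the file.
#' @param time_col,event_col,group_col column names (defaults `"time"`,
#'   `"event"`, `"group"`).
#' @param sep field delimiter (default `","`; use `"\t"` for TSV).
#' @param aliases optional length-2 character vector `c(event, censored)`
#'   naming the strings that encode an event and a censoring, e.g.
#'   `c("dead", "alive")`.
#' @return a [grouped_surv()] object; groups appear in input order.
#' @export
read_survival_table <- function(path, time_col = "time", event_col = "event",
                                group_col = "group", sep = ",",
                                aliases = NULL) {
  if (!file.exists(path)) {
    stop_invalid_input(sprintf("input file '%s' does not exist", path))
  }
  cols <- c(time_col, event_col, group_col)
  if (length(unique(cols)) != 3L) {
    stop_invalid_input("time, event and group column names must be distinct")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  for (col in cols) {
    if (!col %in% names(df)) {
      stop_invalid_input(sprintf("column '%s' not found in '%s'", col, path))
    }
  }
  times <- suppressWarnings(as.numeric(df[[time_col]]))
  bad_time <- which(is.na(times) | !is.finite(times))
  if (length(bad_time)) {
    stop_invalid_input(sprintf(
      "non-numeric or missing time value(s) at data row(s) %s",
      paste(utils::head(bad_time, 5L), collapse = ", ")))
  }
  events <- parse_events(df[[event_col]], aliases)
  bad_ev <- which(is.na(events))
  if (length(bad_ev)) {
    stop_invalid_input(sprintf(
      "event indicator must be 0/1; invalid value(s) at data row(s) %s",
      paste(utils::head(bad_ev, 5L), collapse = ", ")))
  }
  groups <- df[[group_col]]
  if (anyNA(groups)) {
    stop_invalid_input("missing group label(s) in input")
  }
  if (length(unique(groups)) < 2L) {
    stop_invalid_input("need K >= 2 groups to compare medians")
  }
  df2 <- data.frame(time = times, event = events, group = groups,
                    stringsAsFactors = FALSE)
  as_grouped_surv(df2)
}

parse_events <- function(x, aliases = NULL) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    out <- as.integer(x)
    out[!(x %in% c(0, 1))] <- NA_integer_
    return(out)
  }
  xs <- trimws(as.character(x))
  out <- rep(NA_integer_, length(xs))
  out[xs %in% c("1", "TRUE", "true")] <- 1L
  out[xs %in% c("0", "FALSE", "false")] <- 0L
  if (!is.null(aliases)) {
    stopifnot(length(aliases) == 2L)
    out[xs == aliases[1L]] <- 1L
    out[xs == aliases[2L]] <- 0L
  }
  out
}

#' Write grouped survival data as a delimited table
#'
#' Inverse of [read_survival_table()]: writes columns `time`, `event`,
#' `group`, one row per subject, groups in their stored order.
#'
#' @param data a [grouped_surv()] object.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(data, path, sep = ",") {
  rows <- do.call(rbind, lapply(names(data), function(g) {
    data.frame(time = data[[g]]$times, event = data[[g]]$events, group = g,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a deterministic example survival table
#'
#' Produces small survival tables for demonstrations and smoke tests.
#' `"toy_uncensored"` holds two groups each with times 1,2,3,4, all events
#' (a table whose per-group composite variance at the pooled median is
#' exactly 0.09375).  `"toy_censored"` holds two small groups with one
#' censored observation each.  `"scenario:<table>:<row>:<rate>"` writes one
#' replicate drawn from the corresponding catalog scenario (see
#' [scenario_catalog()]), e.g. `"scenario:4:exponential:0.2"`.
#'
#' @param kind fixture kind (see Details).
#' @param seed RNG seed used by scenario fixtures.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
make_fixture <- function(kind, seed = 1L, path) {
  if (kind == "toy_uncensored") {
    data <- grouped_surv(list(
      surv_sample(c(1, 2, 3, 4), c(1, 1, 1, 1), "A"),
      surv_sample(c(1, 2, 3, 4), c(1, 1, 1, 1), "B")))
  } else if (kind == "toy_censored") {
    data <- grouped_surv(list(
      surv_sample(c(1, 2, 3, 5), c(0, 1, 1, 0), "A"),
      surv_sample(c(1, 2, 3, 4), c(1, 1, 0, 1), "B")))
  } else if (grepl("^scenario:", kind)) {
    parts <- strsplit(kind, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 4L) {
      stop_config("scenario fixture kind must be 'scenario:<table>:<row>:<rate>'")
    }
    sc <- scenario_catalog(parts[2L], parts[3L], as.numeric(parts[4L]),
                           reps = 1L, seed = as.integer(seed))
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(sc$seed, kind = "L'Ecuyer-CMRG")
    data <- generate_grouped_data(sc)
  } else {
    stop_config(sprintf(
      "unknown fixture kind '%s'; use toy_uncensored, toy_censored or scenario:<table>:<row>:<rate>",
      kind))
  }
  write_survival_table(data, path)
}
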