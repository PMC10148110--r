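#' Read a survival table
#'
#' TSV schema: \code{sample_id}, \code{time_years} (> 0), \code{event}
#' (1 = death observed, 0 = censored), \code{expression}, \code{stage}
#' (e.g. \code{early}, \code{late}).
#'
#' @param path path to the TSV.
#' @return data.frame with typed columns.
#' @export
readSurvivalTable <- function(path) {
  df <- readTsv(path)
  need <- c("sample_id", "time_years", "event", "expression", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table missing columns: ",
                         paste(miss, collapse = ", "))
  df$time_years <- as.numeric(df$time_years)
  df$event <- as.logical(as.integer(df$event))
  df$expression <- as.numeric(df$expression)
  if (any(!is.finite(df$time_years) | df$time_years <= 0))
    stop("time_years must be finite and positive")
  df
}

#' Dichotomize a cohort at an expression cutoff
#'
#' \code{high} takes expression strictly greater than the cutoff, \code{low}
#' takes the rest; ties therefore go to \code{low} (set
#' \code{high_inclusive = TRUE} for >=). The tie convention is recorded in
#' the result so every run logs which rule was applied.
#'
#' @param records survival data.frame with an \code{expression} column.
#' @param cutoff finite expression cutoff.
#' @param high_inclusive if \code{TRUE}, ties join the high group.
#' @return list: \code{high}, \code{low} (data.frames), \code{convention}.
#' @export
dichotomize <- function(records, cutoff, high_inclusive = FALSE) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  hi <- if (high_inclusive) records$expression >= cutoff
        else records$expression > cutoff
  list(high = records[hi, , drop = FALSE],
       low = records[!hi, , drop = FALSE],
       convention = if (high_inclusive) "high: expression >= cutoff"
                    else "high: expression > cutoff (ties to low)")
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over the distinct
#' event times, via \code{survival::survfit}. Times with only censoring
#' adjust the risk sets but contribute no factor.
#'
#' @param records survival data.frame with \code{time_years} and
#'   \code{event}.
#' @return data.frame, one row per distinct event time: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{surv} (probability after the
#'   time). Zero rows when no event occurs.
#' @export
kmEstimate <- function(records) {
  if (!nrow(records)) stop("no records")
  if (any(records$time_years <= 0)) stop("non-positive survival times")
  fit <- survfit(Surv(time_years, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  out <- out[out$n_event > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-rank test between two survival groups
#'
#' Unweighted log-rank chi-square on 1 degree of freedom, pooling tied event
#' times with the hypergeometric variance at each distinct event time, via
#' \code{survival::survdiff}.
#'
#' @param high,low survival data.frames with \code{time_years} and
#'   \code{event}.
#' @return list: \code{chi2}, \code{p} (two-sided), \code{n_high},
#'   \code{n_low}, \code{events}.
#' @export
logrankTest <- function(high, low) {
  if (!nrow(high) || !nrow(low))
    stop("both groups must be non-empty")
  events <- sum(high$event) + sum(low$event)
  if (events == 0) stop("no events in either group")
  df <- rbind(cbind(high[c("time_years", "event")], group = "high"),
              cbind(low[c("time_years", "event")], group = "low"))
  sd <- survdiff(Surv(time_years, event) ~ group, data = df, rho = 0)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       n_high = nrow(high), n_low = nrow(low), events = events)
}

#' Expression-cutoff survival analysis in one stage stratum
#'
#' Restricts the cohort to a stage stratum (or keeps all samples),
#' dichotomizes at the marker's expression cutoff, estimates both
#' Kaplan-Meier curves and runs the log-rank test. When either group is
#' empty the test is skipped with the reason reported, not an error.
#'
#' @param records survival data.frame (see \code{\link{readSurvivalTable}}).
#' @param cutoff expression cutoff for the high/low split.
#' @param stage \code{"all"} (default) or a stage label to filter on.
#' @param high_inclusive tie convention, see \code{\link{dichotomize}}.
#' @return list: \code{stage}, \code{cutoff}, \code{n_high}, \code{n_low},
#'   \code{km_high}, \code{km_low}, \code{test} (list or \code{NULL}),
#'   \code{skipped} (reason or \code{NULL}).
#' @export
survivalByCutoff <- function(records, cutoff, stage = "all",
                             high_inclusive = FALSE) {
  if (!identical(stage, "all")) {
    records <- records[records$stage %in% stage, , drop = FALSE]
    if (!nrow(records)) stop("no records in stage ", stage)
  }
  split <- dichotomize(records, cutoff, high_inclusive)
  skipped <- NULL
  test <- NULL
  if (!nrow(split$high) || !nrow(split$low)) {
    skipped <- sprintf("empty %s group at cutoff %g",
                       if (nrow(split$high)) "low" else "high", cutoff)
  } else if (sum(split$high$event) + sum(split$low$event) == 0) {
    skipped <- "no events in either group"
  } else {
    test <- logrankTest(split$high, split$low)
  }
  list(stage = if (identical(stage, "all")) "non-stratified" else stage,
       cutoff = cutoff,
       n_high = nrow(split$high), n_low = nrow(split$low),
       km_high = if (nrow(split$high)) kmEstimate(split$high) else NULL,
       km_low = if (nrow(split$low)) kmEstimate(split$low) else NULL,
       test = test, skipped = skipped)
}
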