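#' Median-split stratification
#'
#' Patients with feature value strictly above the median are labelled
#' \code{high}; values at or below the median (ties included) go to
#' \code{low}.
#'
#' @param features Numeric vector (>= 4 values, not all equal).
#' @return Factor with levels \code{low}, \code{high}.
#' @export
medianSplit <- function(features) {
  if (length(features) < 4L)
    stop("median split requires at least 4 patients")
  if (length(unique(features)) == 1L)
    stop("all feature values are equal; median split undefined")
  m <- median(features)
  factor(ifelse(features > m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return data.frame: time, n_risk, n_event, n_censor, surv — one row per
#'   distinct observed time.
#' @export
kmEstimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (any(times < 0)) stop("negative times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time the observed events in arm
#' A are compared with their hypergeometric expectation given the pooled risk
#' sets; the statistic \eqn{(O - E)^2 / V} is referred to chi-square with one
#' degree of freedom. Tied event times enter through the exact hypergeometric
#' variance with multiplicities.
#'
#' @param times_a,events_a Arm A follow-up times and 0/1 event indicators.
#' @param times_b,events_b Arm B.
#' @return list: chi_square, df (= 1), p_value, n_a, n_b.
#' @export
logrankTest <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both arms must be non-empty")
  if (sum(events_a) + sum(events_b) == 0)
    stop("log-rank undefined with zero events")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi_square = unname(sd$chisq), df = 1L,
       p_value = unname(pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
       n_a = length(times_a), n_b = length(times_b))
}

#' Median-split survival contrast for one feature
#'
#' Convenience wrapper chaining \code{\link{medianSplit}} and
#' \code{\link{logrankTest}} over a survival table.
#'
#' @param surv data.frame with columns \code{time}, \code{event} and the
#'   feature named by \code{feature}.
#' @param feature Column name of the stratifying feature.
#' @return list: logrank result plus \code{group} labels and per-group KM
#'   tables.
#' @export
medianSplitSurvival <- function(surv, feature) {
  if (!feature %in% colnames(surv)) stop("unknown feature column: ", feature)
  grp <- medianSplit(surv[[feature]])
  hi <- grp == "high"
  lr <- logrankTest(surv$time[hi], surv$event[hi],
                    surv$time[!hi], surv$event[!hi])
  list(logrank = lr, group = grp,
       km_high = kmEstimate(surv$time[hi], surv$event[hi]),
       km_low = kmEstimate(surv$time[!hi], surv$event[!hi]))
}
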