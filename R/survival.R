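## Kaplan-Meier estimation and the log-rank comparison, implemented
## directly from the risk-set definitions so the survival stage carries
## no dependency beyond base R. Tie convention: deaths at a time t are
## processed before censorings at the same t (both leave the risk set
## after t).

#' Split a cohort by target-gene expression
#'
#' Median split: patients with expression strictly above the cohort
#' median form the high-expression group; ties with the median go to the
#' low-expression group.
#'
#' @param records `data.frame` with an `expression` column (and
#'   typically `time`/`event`; see [simulateSurvival()]).
#' @return List with `high` and `low` data frames.
#' @examples
#' rec <- simulateSurvival(n = 10, seed = 1)
#' lengths(splitByExpression(rec))
#' @export
splitByExpression <- function(records) {
  stopifnot(is.data.frame(records), "expression" %in% names(records),
            nrow(records) >= 2L)
  e <- records$expression
  if (length(unique(e)) == 1L)
    stop("all expression values identical: no split possible")
  med <- median(e)
  list(high = records[e > med, , drop = FALSE],
       low = records[e <= med, , drop = FALSE])
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`
#' where `d_i` is the number of deaths at `t_i` and `n_i` the number at
#' risk just before `t_i`. Censored patients leave the risk set without
#' contributing a step. With no censoring the curve equals the empirical
#' survival function.
#'
#' @param time Non-negative follow-up times.
#' @param event Logical (or 0/1) event indicators, `TRUE` = death.
#' @return A [KMCurve-class].
#' @examples
#' kmEstimate(time = 1:4, event = rep(TRUE, 4))
#' @export
kmEstimate <- function(time, event) {
  if (length(event) == 1L) event <- rep(event, length(time))
  stopifnot(length(time) >= 1L, length(time) == length(event),
            all(time >= 0))
  event <- as.logical(event)
  tt <- sort(unique(time))
  n <- length(time)
  nRisk <- nEvent <- nCensor <- numeric(length(tt))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    nRisk[i] <- sum(time >= tt[i])
    nEvent[i] <- sum(time == tt[i] & event)
    nCensor[i] <- sum(time == tt[i] & !event)
    if (nEvent[i] > 0) s <- s * (1 - nEvent[i] / nRisk[i])
    surv[i] <- s
  }
  new("KMCurve", time = tt, surv = surv, nRisk = nRisk,
      nEvent = nEvent, nCensor = nCensor, n = as.integer(n))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A [KMCurve-class].
#' @param t Times at which to evaluate the step function.
#' @return `S(t)`: 1 before the first observed time, right-continuous
#'   steps thereafter.
#' @export
kmSurvivalAt <- function(curve, t) {
  stopifnot(is(curve, "KMCurve"))
  vapply(t, function(ti) {
    idx <- which(curve@time <= ti)
    if (length(idx) == 0L) 1 else curve@surv[max(idx)]
  }, numeric(1))
}

#' Median overall survival from a Kaplan-Meier curve
#'
#' The smallest observed time at which the survival estimate drops to
#' 0.5 or below; `NA` (with a notice) when the curve never crosses 0.5,
#' i.e. median survival is not reached.
#'
#' @param curve A [KMCurve-class].
#' @return Median survival time, or `NA_real_` when not reached.
#' @export
medianSurvival <- function(curve) {
  stopifnot(is(curve, "KMCurve"))
  idx <- which(curve@surv <= 0.5)
  if (length(idx) == 0L) {
    message("median survival not reached (curve floor above 0.5)")
    return(NA_real_)
  }
  curve@time[min(idx)]
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on 1 degree of freedom over the pooled
#' distinct event times: at each event time the observed deaths in group
#' A are compared with their hypergeometric expectation given the pooled
#' risk set, and the squared summed difference is scaled by the summed
#' hypergeometric variance. Symmetric in the two groups.
#'
#' @param a,b `data.frame`s with `time` and `event` columns (the two
#'   patient groups).
#' @return List with `statistic` (chi-square), `p_value`, `df` (1), and
#'   per-group `observed` and `expected` event counts, so the direction
#'   of any excess mortality is inspectable.
#' @examples
#' rec <- simulateSurvival(n = 30, hazard_ratio = 3, seed = 1)
#' grp <- splitByExpression(rec)
#' logrankTest(grp$high, grp$low)
#' @export
logrankTest <- function(a, b) {
  stopifnot(nrow(a) >= 1L, nrow(b) >= 1L,
            all(c("time", "event") %in% names(a)),
            all(c("time", "event") %in% names(b)))
  evA <- as.logical(a$event); evB <- as.logical(b$event)
  if (!any(evA) && !any(evB))
    stop("no events in either group: log-rank undefined")
  times <- sort(unique(c(a$time[evA], b$time[evB])))
  U <- V <- 0
  obsA <- obsB <- expA <- 0
  for (t in times) {
    n1 <- sum(a$time >= t); n2 <- sum(b$time >= t)
    d1 <- sum(a$time == t & evA); d2 <- sum(b$time == t & evB)
    nn <- n1 + n2; dd <- d1 + d2
    if (nn == 0L || dd == 0L) next
    e1 <- dd * n1 / nn
    U <- U + (d1 - e1)
    if (nn > 1L)
      V <- V + dd * (n1 / nn) * (1 - n1 / nn) * (nn - dd) / (nn - 1)
    obsA <- obsA + d1; obsB <- obsB + d2; expA <- expA + e1
  }
  stat <- if (V > 0) U^2 / V else 0
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L,
       observed = c(a = obsA, b = obsB),
       expected = c(a = expA, b = obsA + obsB - expA))
}

#' Expression-stratified survival comparison
#'
#' The full prognostic analysis: split the cohort at the median
#' target-gene expression, estimate a Kaplan-Meier curve per stratum,
#' compare them with the log-rank test and report median overall
#' survival per stratum.
#'
#' @param records `data.frame` with `expression`, `time` and `event`
#'   columns.
#' @return List with `high` and `low` [KMCurve-class]es, `logrank` (see
#'   [logrankTest()]) and `median_os` (named vector, `NA` when not
#'   reached).
#' @export
survivalByExpression <- function(records) {
  grp <- splitByExpression(records)
  high <- kmEstimate(grp$high$time, grp$high$event)
  low <- kmEstimate(grp$low$time, grp$low$event)
  list(high = high, low = low,
       logrank = logrankTest(grp$high, grp$low),
       median_os = c(high = suppressMessages(medianSurvival(high)),
                     low = suppressMessages(medianSurvival(low))))
}
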