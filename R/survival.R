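#' Kaplan-Meier product-limit estimate
#'
#' Computes `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event
#' times. Subjects censored at an event time remain in the risk set at that
#' time (events precede censorings at ties).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return list with `time` (distinct event times), `survival`, `n_risk`,
#'   `n_event`; class `SurvivalCurve`. With no events the curve is constant
#'   1 and a warning is raised.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (length(times) != length(events)) stop("length mismatch")
  et <- sort(unique(times[events == 1]))
  if (length(et) == 0) {
    warning("no events; survival curve is constant 1")
    return(structure(list(time = numeric(0), survival = numeric(0),
                          n_risk = integer(0), n_event = integer(0)),
                     class = "SurvivalCurve"))
  }
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = et, survival = surv, n_risk = as.integer(n_risk),
                 n_event = as.integer(n_event)),
            class = "SurvivalCurve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param curve a `SurvivalCurve`.
#' @param t times at which to evaluate (right-continuous step function).
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    idx <- which(curve$time <= ti)
    if (length(idx) == 0) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

# Per-event-time log-rank tabulation for two groups; group is logical
# (TRUE = group A). Returns observed-minus-expected and hypergeometric
# variance contributions at each pooled distinct event time.
logrank_table <- function(times, events, group) {
  et <- sort(unique(times[events == 1]))
  o_minus_e <- v <- numeric(length(et))
  for (i in seq_along(et)) {
    t <- et[i]
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group)
    o_minus_e[i] <- d1 - d * n1 / n
    v[i] <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
  }
  list(time = et, o_minus_e = o_minus_e, v = v)
}

#' Two-sample log-rank test
#'
#' Standard (O - E)^2 / V chi-square statistic on 1 degree of freedom,
#' two-sided.
#'
#' @param timesA,eventsA follow-up times and 0/1 event indicators, group A.
#' @param timesB,eventsB same for group B.
#' @return list with `statistic`, `p`, `method = "logrank"`;
#'   class `SurvTestResult`.
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0 || length(timesB) == 0)
    stop("both groups must be nonempty")
  times <- c(timesA, timesB)
  events <- c(eventsA, eventsB)
  if (sum(events) < 1) stop("pooled data contain no events")
  group <- c(rep(TRUE, length(timesA)), rep(FALSE, length(timesB)))
  tab <- logrank_table(times, events, group)
  V <- sum(tab$v)
  stat <- if (V > 0) sum(tab$o_minus_e)^2 / V else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(statistic = stat, p = p, method = "logrank",
                 stage_used = NULL),
            class = "SurvTestResult")
}

# Maximally-selected two-piece weighted log-rank statistic: for each
# candidate crossing time tau, weights are +1 up to tau and -1 after, the
# weighted standardized statistic is |sum(w * (O-E)) / sqrt(sum(w^2 * V))|,
# and the maximum over tau is returned.
two_piece_stat <- function(times, events, group, taus) {
  tab <- logrank_table(times, events, group)
  if (length(tab$time) == 0) return(0)
  best <- 0
  for (tau in taus) {
    w <- ifelse(tab$time <= tau, 1, -1)
    denom <- sqrt(sum(w^2 * tab$v))
    if (denom > 0) best <- max(best, abs(sum(w * tab$o_minus_e)) / denom)
  }
  best
}

#' Two-stage survival test robust to crossing hazards
#'
#' Stage 1 is the log-rank test; if its p-value falls below `alpha1` it is
#' reported directly (`stage_used = 1`). Otherwise stage 2 computes a
#' maximally-selected two-piece weighted log-rank statistic over candidate
#' crossing times (pooled event times between their 10th and 90th
#' percentiles) with a permutation null over group labels
#' (`stage_used = 2`, add-one p estimator with resolution
#' `1 / (n_perm + 1)`). With fewer than 3 candidate crossing times stage 2
#' falls back to the log-rank result with a warning. `alpha1 = 1` reduces
#' the procedure exactly to the log-rank test.
#'
#' @param timesA,eventsA,timesB,eventsB per-group follow-up data.
#' @param alpha1 stage-1 significance threshold (default 0.05).
#' @param n_perm number of label permutations for stage 2 (>= 100).
#' @param seed integer seed making the permutation stream reproducible.
#' @return a `SurvTestResult` with `method = "two_stage"` and `stage_used`.
#' @export
two_stage_test <- function(timesA, eventsA, timesB, eventsB,
                           alpha1 = 0.05, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  s1 <- logrank_test(timesA, eventsA, timesB, eventsB)
  if (s1$p < alpha1 || alpha1 >= 1) {
    return(structure(list(statistic = s1$statistic, p = s1$p,
                          method = "two_stage", stage_used = 1L),
                     class = "SurvTestResult"))
  }
  times <- c(timesA, timesB)
  events <- c(eventsA, eventsB)
  group <- c(rep(TRUE, length(timesA)), rep(FALSE, length(timesB)))
  et <- sort(unique(times[events == 1]))
  qs <- stats::quantile(et, c(0.1, 0.9), names = FALSE, type = 1)
  taus <- et[et >= qs[1] & et <= qs[2]]
  if (length(taus) < 3) {
    warning("too few candidate crossing times; falling back to log-rank")
    return(structure(list(statistic = s1$statistic, p = s1$p,
                          method = "two_stage", stage_used = 1L),
                     class = "SurvTestResult"))
  }
  obs <- two_piece_stat(times, events, group, taus)
  n <- length(times)
  hits <- 0L
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (b in seq_len(n_perm)) {
    gp <- sample(group)
    if (two_piece_stat(times, events, gp, taus) >= obs) hits <- hits + 1L
  }
  p2 <- (1 + hits) / (n_perm + 1)
  structure(list(statistic = obs, p = p2, method = "two_stage",
                 stage_used = 2L),
            class = "SurvTestResult")
}

# Restricted mean survival time: area under the KM curve on [0, tau].
rmst <- function(times, events, tau) {
  curve <- suppressWarnings(km_estimate(times, events))
  tt <- c(0, curve$time[curve$time <= tau], tau)
  ss <- c(1, curve$survival[curve$time <= tau])
  sum(diff(tt) * ss)
}

#' Prognostic call for a gene from mean-cutoff stratified survival
#'
#' Stratifies samples at the mean expression, runs both the log-rank and
#' the two-stage test between the high and low strata, and calls the gene
#' significant when the smaller of the two reported p-values is below
#' `alpha`. Direction is `Poor` when the high-expression stratum has the
#' lower restricted mean survival (up to the last shared follow-up time),
#' otherwise `Better`; non-significant genes are `NS`.
#'
#' @param gene_expr named numeric vector of per-sample expression.
#' @param surv a `SampleTable` with `surv_time` and `surv_event`.
#' @param alpha significance level (default 0.05).
#' @param alpha1,n_perm,seed passed to [two_stage_test()].
#' @return list with `call` in `{Poor, Better, NS}`, `logrank_p`,
#'   `two_stage_p`, `stage_used`, `cutoff`, `n_high`, `n_low`, `reason`.
#' @export
prognostic_call <- function(gene_expr, surv, alpha = 0.05,
                            alpha1 = 0.05, n_perm = 1000, seed = 1) {
  if (!all(c("surv_time", "surv_event") %in% names(surv)))
    stop("sample table lacks survival columns")
  ok <- !is.na(surv$surv_time) & !is.na(surv$surv_event)
  ids <- intersect(surv$sample_id[ok], names(gene_expr))
  if (length(ids) < 4) stop("too few samples with survival data")
  expr <- drop_score_attrs(gene_expr)[ids]
  strat <- tryCatch(stratify_by_mean(expr), error = function(e) NULL)
  if (is.null(strat))
    return(list(call = "NS", logrank_p = NA_real_, two_stage_p = NA_real_,
                stage_used = NA_integer_, cutoff = NA_real_,
                n_high = 0L, n_low = 0L,
                reason = "degenerate stratification"))
  st <- surv[match(ids, surv$sample_id), ]
  hi <- strat$labels == "high"
  tA <- st$surv_time[hi];  eA <- st$surv_event[hi]
  tB <- st$surv_time[!hi]; eB <- st$surv_event[!hi]
  lr <- logrank_test(tA, eA, tB, eB)
  ts <- two_stage_test(tA, eA, tB, eB, alpha1 = alpha1,
                       n_perm = n_perm, seed = seed)
  p_min <- min(lr$p, ts$p)
  call <- "NS"
  if (p_min < alpha) {
    tau <- min(max(tA), max(tB))
    call <- if (rmst(tA, eA, tau) < rmst(tB, eB, tau)) "Poor" else "Better"
  }
  list(call = call, logrank_p = lr$p, two_stage_p = ts$p,
       stage_used = ts$stage_used, cutoff = strat$cutoff,
       n_high = sum(hi), n_low = sum(!hi), reason = "")
}
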