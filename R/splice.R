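#' Percent spliced in from junction counts
#'
#' Length-normalized inclusion level:
#' `PSI = (inc/inc_len) / (inc/inc_len + skip/skip_len)`. Undefined (NA)
#' when both counts are zero. All arguments are vectorized.
#'
#' @param inc,skip non-negative inclusion / skipping junction counts.
#' @param inc_len,skip_len positive effective lengths (defaults 2 and 1,
#'   the junction-count convention for exon skipping).
#' @return PSI values in `[0, 1]`, NA where `inc + skip == 0`.
#' @export
compute_psi <- function(inc, skip, inc_len = 2, skip_len = 1) {
  if (any(inc < 0) || any(skip < 0)) stop("counts must be >= 0")
  if (any(inc_len < 1) || any(skip_len < 1))
    stop("effective lengths must be >= 1")
  ni <- inc / inc_len
  ns <- skip / skip_len
  psi <- ni / (ni + ns)
  psi[inc + skip == 0] <- NA_real_
  psi
}

#' Event x sample PSI matrix
#' @param tab a `SpliceEventTable`.
#' @return numeric matrix of PSI values (NA where both counts are 0).
#' @export
psi_matrix <- function(tab) {
  stopifnot(inherits(tab, "SpliceEventTable"))
  il <- tab$events$inclusion_len
  sl <- tab$events$skipping_len
  psi <- compute_psi(tab$inc, tab$skip, il, sl)
  dimnames(psi) <- dimnames(tab$inc)
  psi
}

#' Filter criteria for the five-rule splice-event chain
#'
#' Defaults are the published cutoffs: group-mean total junction count
#' >= 10 in both groups, cross-sample mean PSI within `[0.05, 0.95]`,
#' FDR <= 0.01, |delta PSI| >= 0.05, and gene TPM >= 1 in at least one
#' group.
#'
#' @param count_min,psi_lo,psi_hi,fdr_max,dpsi_min,tpm_min rule cutoffs.
#' @return list of criteria, class `FilterCriteria`.
#' @export
filter_criteria <- function(count_min = 10, psi_lo = 0.05, psi_hi = 0.95,
                            fdr_max = 0.01, dpsi_min = 0.05, tpm_min = 1) {
  if (psi_lo >= psi_hi) stop("psi_lo must be < psi_hi")
  if (psi_lo < 0 || psi_hi > 1) stop("PSI bounds must lie in [0, 1]")
  if (count_min < 0 || fdr_max < 0 || dpsi_min < 0 || tpm_min < 0)
    stop("criteria must be >= 0")
  structure(list(count_min = count_min, psi_lo = psi_lo, psi_hi = psi_hi,
                 fdr_max = fdr_max, dpsi_min = dpsi_min, tpm_min = tpm_min),
            class = "FilterCriteria")
}

# Beta-binomial log-likelihood for inclusion counts k of totals n with mean
# mu and dispersion rho (rho -> 0 recovers the binomial).
bb_loglik <- function(k, n, mu, rho) {
  if (mu <= 0 || mu >= 1 || rho < 0 || rho >= 1) return(-Inf)
  if (rho < 1e-12) {
    return(sum(lchoose(n, k) + k * log(mu) + (n - k) * log(1 - mu)))
  }
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

# Profile maximization of the beta-binomial likelihood at fixed dispersion:
# the mean is a 1-D concave problem solved by optimize to high precision.
bb_profile_mu <- function(k, n, rho, eps = 1e-9) {
  if (sum(k) == 0) return(list(mu = eps, loglik = bb_loglik(k, n, eps, rho)))
  if (sum(k) == sum(n))
    return(list(mu = 1 - eps, loglik = bb_loglik(k, n, 1 - eps, rho)))
  if (rho < 1e-12) {
    mu <- sum(k) / sum(n)   # binomial MLE is closed form
    return(list(mu = mu, loglik = bb_loglik(k, n, mu, 0)))
  }
  opt <- stats::optimize(function(m) bb_loglik(k, n, m, rho),
                         c(eps, 1 - eps), maximum = TRUE, tol = 1e-10)
  list(mu = opt$maximum, loglik = opt$objective)
}

# Maximize one model's likelihood over its means and the shared dispersion
# by nesting precise 1-D optimizations: the inner problem profiles the
# mean(s) at fixed rho, the outer maximizes over rho with the binomial
# boundary (rho = 0) checked explicitly.
bb_profile_fit <- function(k, n, g = NULL, rho_fixed = NULL) {
  prof <- if (is.null(g)) {
    function(rho) bb_profile_mu(k, n, rho)$loglik
  } else {
    function(rho) bb_profile_mu(k[g == 1], n[g == 1], rho)$loglik +
      bb_profile_mu(k[g == 2], n[g == 2], rho)$loglik
  }
  if (!is.null(rho_fixed)) return(list(rho = rho_fixed,
                                       loglik = prof(rho_fixed)))
  opt <- tryCatch(
    stats::optimize(prof, c(1e-9, 0.9), maximum = TRUE, tol = 1e-8),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) return(NULL)
  ll_bound <- prof(0)
  if (ll_bound >= opt$objective) list(rho = 0, loglik = ll_bound)
  else list(rho = opt$maximum, loglik = opt$objective)
}

# Shared-dispersion likelihood-ratio fit for one event: the dispersion is
# estimated under the group-means alternative and held fixed in the
# pooled-mean null fit, so the ratio contrasts means at a common
# dispersion (the null otherwise absorbs a real group difference into an
# inflated dispersion estimate and the test loses most of its power).
# The resulting statistic needs the Bartlett-style mean calibration
# applied in bb_lrt().
bb_fit_event <- function(k, n, g, rho_fixed = NULL) {
  f1 <- bb_profile_fit(k, n, g, rho_fixed)
  if (is.null(f1) || !is.finite(f1$loglik))
    return(list(converged = FALSE))
  if (is.null(rho_fixed) && f1$rho == 0) {
    # boundary dispersion estimate: the plug-in rationale fails (a truly
    # overdispersed event misread as binomial explodes the pooled fit),
    # so profile the null's dispersion freely instead
    f0 <- bb_profile_fit(k, n, NULL, NULL)
    if (is.null(f0) || !is.finite(f0$loglik))
      return(list(converged = FALSE))
    mu0 <- bb_profile_mu(k, n, f0$rho)$mu
    return(list(converged = TRUE, rho = f0$rho,
                loglik_alt = f1$loglik, loglik_null = f0$loglik, mu0 = mu0))
  }
  f0 <- bb_profile_mu(k, n, f1$rho)
  if (!is.finite(f0$loglik)) return(list(converged = FALSE))
  list(converged = TRUE, rho = f1$rho,
       loglik_alt = f1$loglik, loglik_null = f0$loglik, mu0 = f0$mu)
}

#' Beta-binomial likelihood-ratio test for differential splicing
#'
#' For each event, inclusion counts are modeled as beta-binomial draws of
#' the per-sample totals with a dispersion shared between groups: the null
#' fits one common mean inclusion level, the alternative group-specific
#' means (dispersion estimated under the alternative and held fixed in the
#' null fit). The LRT statistic `2(l1 - l0)` is referred to chi-square
#' with 1 df after a Bartlett-style mean calibration: a parametric
#' bootstrap under the fitted nulls estimates the finite-sample mean of
#' the statistic and the statistic is rescaled so that mean matches the
#' chi-square expectation (small replicate numbers otherwise inflate the
#' test). P-values are BH-adjusted across events. Samples with zero total
#' are excluded per event; events with fewer than 2 usable replicates in
#' either group are skipped (NA p, flagged). Non-convergent fits get
#' p = 1 with a flag.
#'
#' @param tab a `SpliceEventTable`.
#' @param groups named character vector sample id -> group label (exactly
#'   two labels); order of `sort(unique())` defines group 1 vs 2.
#' @param rho_fixed optionally pin the dispersion (0 = pure binomial LRT).
#' @param calibrate apply the bootstrap Bartlett correction (default TRUE;
#'   FALSE refers the raw statistic to chi-square df 1).
#' @param n_boot minimum number of bootstrap null statistics used to
#'   estimate the correction factor.
#' @param seed seed for the bootstrap stream (restored afterwards).
#' @return data.frame per event: `event_id`, `psi_mean_g1`, `psi_mean_g2`,
#'   `delta_psi`, `lrt_stat` (raw LRT), `p`, `fdr`, `rho`, `flag`;
#'   attribute `bartlett` carries the calibration factor.
#' @export
bb_lrt <- function(tab, groups, rho_fixed = NULL, calibrate = TRUE,
                   n_boot = 800, seed = 1L) {
  stopifnot(inherits(tab, "SpliceEventTable"))
  samples <- intersect(colnames(tab$inc), names(groups))
  glab <- sort(unique(as.character(groups[samples])))
  if (length(glab) != 2) stop("exactly two groups required")
  g <- as.integer(factor(as.character(groups[samples]), levels = glab))
  psi <- psi_matrix(tab)[, samples, drop = FALSE]
  n_ev <- nrow(tab$events)
  out <- data.frame(event_id = tab$events$event_id,
                    psi_mean_g1 = NA_real_, psi_mean_g2 = NA_real_,
                    delta_psi = NA_real_, lrt_stat = NA_real_,
                    p = NA_real_, fdr = NA_real_, rho = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  fits <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    k <- tab$inc[i, samples]
    n <- k + tab$skip[i, samples]
    use <- n > 0
    if (sum(use & g == 1) < 2 || sum(use & g == 2) < 2) {
      out$flag[i] <- "too_few_replicates"
      next
    }
    ku <- k[use]; nu <- n[use]; gu <- g[use]
    out$psi_mean_g1[i] <- mean(psi[i, samples][use & g == 1])
    out$psi_mean_g2[i] <- mean(psi[i, samples][use & g == 2])
    out$delta_psi[i] <- out$psi_mean_g1[i] - out$psi_mean_g2[i]
    fit <- bb_fit_event(ku, nu, gu, rho_fixed = rho_fixed)
    if (!fit$converged) {
      out$p[i] <- 1
      out$lrt_stat[i] <- 0
      out$flag[i] <- "non_convergence"
      next
    }
    stat <- max(0, 2 * (fit$loglik_alt - fit$loglik_null))
    out$lrt_stat[i] <- stat
    out$p[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    out$rho[i] <- fit$rho
    fits[[i]] <- fit
  }
  bartlett <- 1
  tested <- which(!is.na(out$p) & out$flag == "")
  if (calibrate && length(tested) > 0) {
    bartlett <- bb_bartlett_factor(tab, samples, g, tested, fits,
                                   rho_fixed, n_boot, seed)
    out$p[tested] <- stats::pchisq(out$lrt_stat[tested] / bartlett, df = 1,
                                   lower.tail = FALSE)
  }
  has_p <- !is.na(out$p)
  out$fdr[has_p] <- stats::p.adjust(out$p[has_p], method = "BH")
  attr(out, "bartlett") <- bartlett
  out
}

# Parametric-bootstrap estimate of the finite-sample null mean of the LRT
# statistic: events are resampled from their fitted pooled-mean null
# (observed totals kept fixed) and refit, and the mean statistic over all
# draws is the Bartlett factor (floored at 1 so calibration never makes
# the test more liberal than the asymptotic reference).
bb_bartlett_factor <- function(tab, samples, g, tested, fits,
                               rho_fixed, n_boot, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  reps <- max(1L, ceiling(n_boot / length(tested)))
  idx <- rep(tested, reps)
  stats_null <- numeric(length(idx))
  pos <- 0L
  for (i in idx) {
    fit <- fits[[i]]
    k <- tab$inc[i, samples]
    n <- k + tab$skip[i, samples]
    use <- n > 0
    nu <- n[use]; gu <- g[use]
    mu <- min(max(fit$mu0, 1e-6), 1 - 1e-6)
    rho <- fit$rho
    kstar <- if (rho > 0) {
      a <- mu * (1 - rho) / rho
      b <- (1 - mu) * (1 - rho) / rho
      stats::rbinom(length(nu), nu, stats::rbeta(length(nu), a, b))
    } else stats::rbinom(length(nu), nu, mu)
    f <- bb_fit_event(kstar, nu, gu, rho_fixed = rho_fixed)
    pos <- pos + 1L
    stats_null[pos] <- if (f$converged)
      max(0, 2 * (f$loglik_alt - f$loglik_null)) else NA_real_
  }
  max(1, mean(stats_null, na.rm = TRUE))
}

#' Apply the five-rule splice-event filter chain
#'
#' Rules in order: (1) group-mean total junction count >= `count_min` in
#' both groups; (2) cross-sample mean PSI within `[psi_lo, psi_hi]`;
#' (3) FDR <= `fdr_max`; (4) |delta PSI| >= `dpsi_min`; (5) gene TPM >=
#' `tpm_min` in at least one group (skipped when the table carries no TPM
#' columns). Untested events (NA p) are removed up front. Attrition at each
#' rule is recorded.
#'
#' @param tests output of [bb_lrt()].
#' @param tab the `SpliceEventTable` the tests were computed from.
#' @param groups the same sample -> group assignment used for the test.
#' @param fc a [filter_criteria()] bundle.
#' @return list with `kept` (filtered `tests` rows, with `event_class`
#'   merged in), `attrition` (named integer vector per rule), `n_input`.
#' @export
filter_events <- function(tests, tab, groups, fc = filter_criteria()) {
  stopifnot(inherits(fc, "FilterCriteria"), inherits(tab, "SpliceEventTable"))
  if (!setequal(tests$event_id, tab$events$event_id))
    stop("tests and event table must share the same event universe")
  ord <- match(tests$event_id, tab$events$event_id)
  samples <- intersect(colnames(tab$inc), names(groups))
  glab <- sort(unique(as.character(groups[samples])))
  g <- as.character(groups[samples])
  tot <- (tab$inc + tab$skip)[ord, samples, drop = FALSE]
  psi <- psi_matrix(tab)[ord, samples, drop = FALSE]

  keep <- !is.na(tests$p)
  attrition <- c(untested = sum(!keep))

  mean_tot_ok <- rep(TRUE, nrow(tot))
  for (lab in glab)
    mean_tot_ok <- mean_tot_ok &
      rowMeans(tot[, g == lab, drop = FALSE]) >= fc$count_min
  pass <- keep & mean_tot_ok
  attrition["rule1_count"] <- sum(keep) - sum(pass)
  keep <- pass

  mpsi <- rowMeans(psi, na.rm = TRUE)
  pass <- keep & !is.na(mpsi) & mpsi >= fc$psi_lo & mpsi <= fc$psi_hi
  attrition["rule2_psi_range"] <- sum(keep) - sum(pass)
  keep <- pass

  pass <- keep & tests$fdr <= fc$fdr_max
  attrition["rule3_fdr"] <- sum(keep) - sum(pass, na.rm = TRUE)
  keep <- pass & !is.na(pass)

  pass <- keep & abs(tests$delta_psi) >= fc$dpsi_min
  attrition["rule4_dpsi"] <- sum(keep) - sum(pass)
  keep <- pass

  if (!is.null(tab$tpm)) {
    tpm_ok <- apply(tab$tpm[ord, , drop = FALSE] >= fc$tpm_min, 1, any)
    pass <- keep & tpm_ok
    attrition["rule5_tpm"] <- sum(keep) - sum(pass)
    keep <- pass
  } else {
    attrition["rule5_tpm"] <- 0L
  }

  kept <- tests[keep, , drop = FALSE]
  kept$event_class <- tab$events$event_class[ord][keep]
  list(kept = kept, attrition = attrition, n_input = nrow(tests))
}

#' Event-class composition of a filtered event set
#'
#' @param event_class character vector of event classes, or a data.frame
#'   with an `event_class` column (e.g. `filter_events()$kept`).
#' @return list with `counts` and `proportions` over the five classes
#'   (SE, RI, MXE, A3SS, A5SS); proportions sum to 1.
#' @export
event_composition <- function(event_class) {
  if (is.data.frame(event_class)) event_class <- event_class$event_class
  if (length(event_class) == 0) stop("empty event set")
  classes <- c("SE", "RI", "MXE", "A3SS", "A5SS")
  if (!all(event_class %in% classes)) stop("unknown event_class value")
  counts <- table(factor(event_class, levels = classes))
  list(counts = as.integer(counts) |> stats::setNames(classes),
       proportions = as.numeric(counts / sum(counts)) |>
         stats::setNames(classes))
}

#' Split a filtered event set by delta-PSI sign
#'
#' @param kept data.frame with a `delta_psi` column (from
#'   `filter_events()$kept`).
#' @return list with `n_up` (delta PSI > 0), `n_down` (< 0), `n_total`.
#' @export
direction_split <- function(kept) {
  if (nrow(kept) == 0) stop("empty event set")
  list(n_up = sum(kept$delta_psi > 0), n_down = sum(kept$delta_psi < 0),
       n_total = nrow(kept))
}
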