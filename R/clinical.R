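#' Association between a per-sample quantity and a clinical covariate
#'
#' Binary covariates are tested with the two-sided Wilcoxon rank-sum test
#' (exact when both groups have n <= 10 and no ties, normal approximation
#' with tie correction otherwise); covariates with three or more categories
#' use the Kruskal-Wallis chi-square approximation. Missing covariate
#' values are dropped pairwise; categories emptied by filtering are dropped
#' with a note.
#'
#' @param values named numeric vector (sample id -> value).
#' @param covariate vector over the same samples (values may contain NA).
#' @return list with `method` ("wilcoxon" or "kruskal"), `statistic`, `p`,
#'   `n_per_group`, and `dropped` (categories removed for emptiness).
#' @export
clinical_association <- function(values, covariate) {
  if (length(values) != length(covariate))
    stop("values and covariate must have equal length")
  keep <- !is.na(values) & !is.na(covariate)
  v <- as.numeric(values[keep])
  g <- factor(as.character(covariate[keep]))
  dropped <- setdiff(levels(factor(as.character(covariate))), levels(droplevels(g)))
  g <- droplevels(g)
  tab <- table(g)
  if (length(tab) < 2)
    stop("fewer than 2 nonempty categories after dropping missing values")
  if (length(tab) == 2) {
    a <- v[g == levels(g)[1]]
    b <- v[g == levels(g)[2]]
    exact <- length(a) <= 10 && length(b) <= 10 && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = !exact))
    res <- list(method = "wilcoxon", statistic = unname(wt$statistic),
                p = wt$p.value)
  } else {
    kt <- stats::kruskal.test(v, g)
    res <- list(method = "kruskal", statistic = unname(kt$statistic),
                p = kt$p.value)
  }
  res$n_per_group <- as.integer(tab)
  names(res$n_per_group) <- names(tab)
  res$dropped <- dropped
  res
}

#' Drug-sensitivity association calls
#'
#' For each drug, compares IC50 values between high- and low-score strata
#' (Wilcoxon rank-sum) and correlates IC50 with the axis score (Pearson).
#' A call is issued only when the two views agree:
#' `reduced_sensitivity` when p < alpha, median(high) > median(low) and
#' r > 0 (higher IC50 in high-score patients, i.e. less sensitive);
#' `enhanced_sensitivity` for the mirror pattern; otherwise `no_call`.
#'
#' @param ic50 numeric matrix, drugs x samples.
#' @param axis_scores named numeric vector of the axis score per sample.
#' @param labels a `StratifiedLabels` object (from [stratify_by_mean()]).
#' @param alpha significance level for the stratified test (default 0.05).
#' @return data.frame `drug`, `p`, `r`, `median_high`, `median_low`, `class`.
#' @export
drug_association <- function(ic50, axis_scores, labels, alpha = 0.05) {
  stopifnot(is.matrix(ic50), inherits(labels, "StratifiedLabels"))
  s <- drop_score_attrs(axis_scores)
  samples <- intersect(colnames(ic50), names(labels$labels))
  samples <- intersect(samples, names(s))
  hi <- samples[labels$labels[samples] == "high"]
  lo <- samples[labels$labels[samples] == "low"]
  if (length(hi) < 3 || length(lo) < 3)
    stop("need >= 3 samples per stratum for drug association")
  res <- lapply(rownames(ic50), function(drug) {
    x <- ic50[drug, samples]
    if (stats::sd(x) == 0)
      return(data.frame(drug = drug, p = NA_real_, r = NA_real_,
                        median_high = stats::median(x[hi]),
                        median_low = stats::median(x[lo]),
                        class = "no_call", reason = "constant IC50",
                        stringsAsFactors = FALSE))
    wt <- suppressWarnings(
      stats::wilcox.test(x[hi], x[lo], alternative = "two.sided"))
    r <- stats::cor(x, s[samples])
    mh <- stats::median(x[hi]); ml <- stats::median(x[lo])
    cls <- "no_call"
    if (!is.na(wt$p.value) && wt$p.value < alpha) {
      if (mh > ml && r > 0) cls <- "reduced_sensitivity"
      if (mh < ml && r < 0) cls <- "enhanced_sensitivity"
    }
    data.frame(drug = drug, p = wt$p.value, r = r, median_high = mh,
               median_low = ml, class = cls, reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
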