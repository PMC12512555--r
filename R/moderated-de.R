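#' Moderated two-group differential expression
#'
#' Per-gene two-group linear model on log2(TPM + 1.01) values: the log2 fold
#' change is the difference of group means (tumor minus normal), per-gene
#' residual variances are shrunk toward a common prior by empirical Bayes
#' (a scaled inverse chi-square prior whose hyperparameters `d0`, `s0^2` are
#' fit by method of moments on the log residual variances), and the
#' moderated t-statistic is referred to a t distribution with `d + d0`
#' degrees of freedom. P-values are Benjamini-Hochberg adjusted across genes.
#'
#' @param m an `ExpressionMatrix` in log2 space.
#' @param groups character/factor vector over the matrix samples with
#'   levels `tumor` and `normal` (or any two labels; `contrast` names the
#'   level whose mean comes first in the fold change).
#' @param contrast label treated as the "case" group (default `"tumor"`).
#' @param prior_df override for the prior degrees of freedom `d0`: `NULL`
#'   (fit by method of moments), `0` (ordinary pooled t), or `Inf`.
#' @return data.frame with one row per gene: `gene_id`, `log2fc`, `t_stat`,
#'   `df_total`, `p`, `adj_p`; attributes `prior_df` and `prior_var` carry
#'   the fitted hyperparameters.
#' @export
moderated_de <- function(m, groups, contrast = "tumor", prior_df = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$space != "log2") stop("moderated_de requires a log2-space matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(m$values))
    stop("`groups` length must match the number of samples")
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (!contrast %in% lv) stop("`contrast` level not present in `groups`")
  other <- setdiff(lv, contrast)
  i1 <- which(groups == contrast)
  i2 <- which(groups == other)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  d <- n1 + n2 - 2
  if (d < 1) stop("zero residual degrees of freedom")

  x <- m$values
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  lfc <- m1 - m2
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d

  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2, d)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(d0) && d0 > 0) fit_variance_prior(s2, d)$s02
           else exp(mean(log(pmax(s2, 1e-300))))
  }

  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- rep(d, length(s2))
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- rep(d + d0, length(s2))
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  p[se == 0 & lfc == 0] <- 1
  adj_p <- stats::p.adjust(p, method = "BH")

  out <- data.frame(gene_id = gene_ids(m), log2fc = lfc, t_stat = t_stat,
                    df_total = df_total, p = p, adj_p = adj_p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

#' Fit the scaled inverse chi-square variance prior by method of moments
#'
#' Given per-gene residual variances `s2` on `d` residual degrees of
#' freedom, matches the first two moments of `log(s2)` against the
#' log-F distribution implied by the hierarchical model, yielding prior
#' degrees of freedom `d0` and prior variance `s02`. When the observed
#' spread of log variances does not exceed its sampling expectation the
#' prior is degenerate (`d0 = Inf`).
#'
#' @param s2 numeric vector of residual variances (> 0 where informative).
#' @param d residual degrees of freedom (scalar).
#' @return list with `d0` and `s02`.
#' @export
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2) stop("need >= 2 positive residual variances to fit prior")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2) * n / (n - 1) - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s02 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(y) = x (monotone decreasing, convex).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
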