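#' Per-sample splicing-factor activity score
#'
#' The splicing score of a sample is the unweighted arithmetic mean of its
#' log2(TPM + 1.01) expression over a curated set of splicing regulatory
#' factors. Genes in the set that are absent from the matrix are dropped;
#' the number found is recorded in the `n_found` attribute.
#'
#' @param m an `ExpressionMatrix` in log2 space.
#' @param factors a `GeneSet` of splicing regulatory factors.
#' @return named numeric vector of per-sample scores with attributes
#'   `score_name`, `n_found`, `n_set`.
#' @export
splicing_score <- function(m, factors) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(factors, "GeneSet"))
  if (m$space != "log2") stop("splicing score requires a log2-space matrix")
  hit <- intersect(factors$members, gene_ids(m))
  if (length(hit) == 0)
    stop("no splicing-factor genes found in the expression matrix")
  if (length(hit) < 0.5 * length(factors$members))
    warning(sprintf("only %d of %d splicing factors found in the matrix",
                    length(hit), length(factors$members)))
  s <- colMeans(m$values[hit, , drop = FALSE])
  structure(s, score_name = "splicing_score",
            n_found = length(hit), n_set = length(factors$members))
}

#' mRNA stemness index (mRNAsi-style one-class signature score)
#'
#' The raw per-sample score is the Spearman rank correlation between the
#' signature weight vector and the sample's expression over the signature
#' genes shared with the matrix; raw scores are then linearly rescaled
#' cohort-wide so the minimum maps to 0 and the maximum to 1. The
#' correlation kernel is pluggable via `method` (`"spearman"` default,
#' `"pearson"` available).
#'
#' @param m an `ExpressionMatrix` in log2 space.
#' @param w a `SignatureWeights` vector.
#' @param method correlation kernel for the raw score.
#' @return named numeric vector of scores in `[0, 1]` with attributes
#'   `raw` (unscaled correlations) and `n_genes` (signature genes used).
#' @export
stemness_index <- function(m, w, method = c("spearman", "pearson")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  method <- match.arg(method)
  if (m$space != "log2") stop("stemness index requires a log2-space matrix")
  shared <- intersect(names(w), gene_ids(m))
  if (length(shared) < 3)
    stop("fewer than 3 signature genes present in the expression matrix")
  wv <- as.numeric(w[shared])
  expr <- m$values[shared, , drop = FALSE]
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0))
    stop("constant expression across signature genes in sample(s): ",
         paste(colnames(expr)[sds == 0], collapse = ", "))
  raw <- apply(expr, 2, function(x) stats::cor(wv, x, method = method))
  rng <- range(raw)
  if (rng[1] == rng[2])
    stop("all raw stemness scores identical; 0-1 rescale undefined")
  s <- (raw - rng[1]) / (rng[2] - rng[1])
  structure(s, score_name = "stemness_index", raw = raw,
            n_genes = length(shared))
}

#' Stratify samples into high/low groups at the mean score
#'
#' The cohort mean of the score is the cutoff; samples strictly above it are
#' labeled `high`, all others (including exact ties with the mean) `low`.
#'
#' @param s named numeric score vector (>= 2 samples).
#' @return list with `labels` (named character, "high"/"low") and
#'   `cutoff`; class `StratifiedLabels`.
#' @export
stratify_by_mean <- function(s) {
  s <- drop_score_attrs(s)
  if (length(s) < 2) stop("need >= 2 samples to stratify")
  if (anyNA(s) || any(!is.finite(s))) stop("scores must be finite")
  cutoff <- mean(s)
  if (all(s == s[1])) stop("all scores identical; stratification degenerate")
  labels <- ifelse(s > cutoff, "high", "low")
  structure(list(labels = labels, cutoff = cutoff),
            class = "StratifiedLabels")
}

drop_score_attrs <- function(s) {
  out <- as.numeric(s)
  names(out) <- names(s)
  out
}

#' Classify cells as cancer stem cells from differentiation-potential scores
#'
#' Cells scoring strictly above `hi` are called `CSC`, strictly below `lo`
#' `nonCSC`; the band `[lo, hi]` is labeled `intermediate` and intended to
#' be excluded from two-group contrasts.
#'
#' @param diff_scores named numeric vector of differentiation-potential
#'   scores in `[0, 1]` (e.g. CytoTRACE output).
#' @param hi,lo classification thresholds, `hi > lo` (defaults 0.8 / 0.6).
#' @return named character vector in `{CSC, nonCSC, intermediate}`.
#' @export
classify_csc <- function(diff_scores, hi = 0.8, lo = 0.6) {
  s <- drop_score_attrs(diff_scores)
  if (hi <= lo) stop("`hi` must exceed `lo`")
  if (any(s < 0 | s > 1)) stop("differentiation scores must lie in [0, 1]")
  out <- rep("intermediate", length(s))
  out[s > hi] <- "CSC"
  out[s < lo] <- "nonCSC"
  names(out) <- names(s)
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`, with midranks for tied scores.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1, logical, or two-level factor); the
#'   larger/TRUE/second level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- drop_score_attrs(scores)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both label classes must be present")
  r <- rank(scores)  # midranks for ties
  u <- sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}
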