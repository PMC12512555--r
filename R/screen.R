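#' Screen threshold bundle
#'
#' The composite cutoffs driving candidate selection: differential-expression
#' thresholds (|log2FC| > 0.6, adjusted p < 0.001), stemness-correlation
#' bounds (+0.25 / -0.25), splicing-correlation bounds (+0.45 / -0.25), and
#' the correlation p cutoff (0.05). Defaults are the published values.
#'
#' @param lfc_min minimum |log2FC| for a DE call.
#' @param adjp_max maximum BH-adjusted DE p-value.
#' @param r_stem_pos,r_stem_neg stemness-correlation bounds (pos > 0 > neg).
#' @param r_splice_pos,r_splice_neg splicing-correlation bounds.
#' @param p_corr_max maximum (raw) correlation p-value.
#' @return list of thresholds, class `ScreenThresholds`.
#' @export
screen_thresholds <- function(lfc_min = 0.6, adjp_max = 0.001,
                              r_stem_pos = 0.25, r_stem_neg = -0.25,
                              r_splice_pos = 0.45, r_splice_neg = -0.25,
                              p_corr_max = 0.05) {
  if (lfc_min <= 0) stop("lfc_min must be > 0")
  if (r_stem_pos <= 0 || r_splice_pos <= 0)
    stop("positive correlation thresholds must be > 0")
  if (r_stem_neg >= 0 || r_splice_neg >= 0)
    stop("negative correlation thresholds must be < 0")
  if (adjp_max <= 0 || adjp_max > 1 || p_corr_max <= 0 || p_corr_max > 1)
    stop("p-value cutoffs must lie in (0, 1]")
  structure(list(lfc_min = lfc_min, adjp_max = adjp_max,
                 r_stem_pos = r_stem_pos, r_stem_neg = r_stem_neg,
                 r_splice_pos = r_splice_pos, r_splice_neg = r_splice_neg,
                 p_corr_max = p_corr_max),
            class = "ScreenThresholds")
}

#' Correlate every gene with a per-sample axis score
#'
#' Pearson correlation between each gene's log2 expression and a score
#' vector (splicing score or stemness index), with the two-sided p-value
#' from the t transform on `n - 2` degrees of freedom. Genes with zero
#' variance over the used samples get `NA` and are flagged in the
#' `excluded` attribute (they can never pass the screen).
#'
#' @param m an `ExpressionMatrix` in log2 space.
#' @param s named numeric score vector (sample id -> score).
#' @param restrict_to optional character vector of sample ids to use
#'   (e.g. tumor samples only).
#' @return data.frame `gene_id`, `r`, `p` with attribute `excluded`
#'   (gene ids with constant expression) and `n_samples`.
#' @export
correlate_with_score <- function(m, s, restrict_to = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$space != "log2") stop("correlations expect a log2-space matrix")
  s <- drop_score_attrs(s)
  use <- intersect(sample_ids_of(m), names(s))
  if (!is.null(restrict_to)) use <- intersect(use, restrict_to)
  n <- length(use)
  if (n < 3) stop("need >= 3 overlapping samples for correlation")
  sv <- s[use]
  if (stats::sd(sv) == 0) stop("score vector is constant over the used samples")
  x <- m$values[, use, drop = FALSE]
  xc <- x - rowMeans(x)
  sc <- sv - mean(sv)
  denom <- sqrt(rowSums(xc^2) * sum(sc^2))
  r <- as.numeric(xc %*% sc) / ifelse(denom > 0, denom, NA_real_)
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- .Machine$double.xmin
  excluded <- gene_ids(m)[denom == 0]
  out <- data.frame(gene_id = gene_ids(m), r = r, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "n_samples") <- n
  out
}

#' Select concordant candidate lncRNAs
#'
#' A gene is `up_concordant` when it is significantly upregulated
#' (log2FC > `lfc_min`, adj p < `adjp_max`) and positively correlated with
#' both the stemness index (r > `r_stem_pos`) and the splicing score
#' (r > `r_splice_pos`) at `p < p_corr_max`; `down_concordant` mirrors all
#' five conditions. Genes flagged as constant in either correlation table
#' are never selected.
#'
#' @param de data.frame from [moderated_de()].
#' @param c_stem,c_splice data.frames from [correlate_with_score()] against
#'   the stemness and splicing scores.
#' @param th a [screen_thresholds()] bundle.
#' @return data.frame of selected genes with `direction` and the passing
#'   statistics; attribute `n_up` / `n_down` summarize counts.
#' @export
select_candidates <- function(de, c_stem, c_splice, th = screen_thresholds()) {
  stopifnot(inherits(th, "ScreenThresholds"))
  if (!setequal(de$gene_id, c_stem$gene_id) ||
      !setequal(de$gene_id, c_splice$gene_id))
    stop("DE and correlation tables must share the same gene universe")
  cs <- c_stem[match(de$gene_id, c_stem$gene_id), ]
  cp <- c_splice[match(de$gene_id, c_splice$gene_id), ]
  ok <- !is.na(cs$r) & !is.na(cp$r)
  up <- ok &
    de$log2fc > th$lfc_min & de$adj_p < th$adjp_max &
    cs$r > th$r_stem_pos & cs$p < th$p_corr_max &
    cp$r > th$r_splice_pos & cp$p < th$p_corr_max
  down <- ok &
    de$log2fc < -th$lfc_min & de$adj_p < th$adjp_max &
    cs$r < th$r_stem_neg & cs$p < th$p_corr_max &
    cp$r < th$r_splice_neg & cp$p < th$p_corr_max
  sel <- up | down
  out <- data.frame(gene_id = de$gene_id[sel],
                    direction = ifelse(up[sel], "up_concordant",
                                       "down_concordant"),
                    log2fc = de$log2fc[sel], adj_p = de$adj_p[sel],
                    r_stem = cs$r[sel], p_stem = cs$p[sel],
                    r_splice = cp$r[sel], p_splice = cp$p[sel],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_up") <- sum(up)
  attr(out, "n_down") <- sum(down)
  attr(out, "thresholds") <- th
  out
}

#' Write screen output as TSV plus a JSON summary
#'
#' @param candidates output of [select_candidates()].
#' @param tsv_path,json_path output file paths (either may be NULL to skip).
#' @export
write_screen_output <- function(candidates, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(candidates, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    th <- attr(candidates, "thresholds")
    jsonlite::write_json(
      list(n_up = attr(candidates, "n_up"),
           n_down = attr(candidates, "n_down"),
           thresholds = unclass(th)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(candidates)
}
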