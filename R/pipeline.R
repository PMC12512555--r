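#' Validate a pipeline run configuration
#'
#' Reads a YAML (or JSON) configuration, fills published defaults for any
#' absent threshold, and checks paths and invariants. Recognized keys:
#' `inputs` (paths: `expression`, `samples`, `factors`, `weights`,
#' optionally `events`, `event_groups`, `ic50`), `thresholds` (fields of
#' [screen_thresholds()]), `filter` (fields of [filter_criteria()]),
#' `survival` (`alpha`, `alpha1`, `n_perm`), `correlation_samples`
#' (`"tumor"` or `"all"`), `seed`, `outdir`. Unknown keys are an error.
#'
#' @param path configuration file path.
#' @return validated configuration list, class `RunConfig`.
#' @export
validate_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("inputs", "thresholds", "filter", "survival",
             "correlation_samples", "seed", "outdir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(raw$inputs)) stop("config needs an `inputs` section")
  need <- c("expression", "samples", "factors", "weights")
  miss <- setdiff(need, names(raw$inputs))
  if (length(miss)) stop("config inputs missing: ", paste(miss, collapse = ", "))
  for (nm in names(raw$inputs)) {
    if (!file.exists(raw$inputs[[nm]]))
      stop("input file does not exist: ", nm, " = ", raw$inputs[[nm]])
  }
  th <- do.call(screen_thresholds, as.list(raw$thresholds))
  fc <- do.call(filter_criteria, as.list(raw$filter))
  sv <- raw$survival
  if (is.null(sv)) sv <- list()
  sv <- utils::modifyList(list(alpha = 0.05, alpha1 = 0.05, n_perm = 1000), sv)
  corr_on <- if (is.null(raw$correlation_samples)) "tumor"
             else match.arg(raw$correlation_samples, c("tumor", "all"))
  structure(list(inputs = raw$inputs, thresholds = th, filter = fc,
                 survival = sv, correlation_samples = corr_on,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 outdir = if (is.null(raw$outdir)) "." else raw$outdir),
            class = "RunConfig")
}

#' Write a RunConfig back to YAML
#' @param cfg a `RunConfig`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  out <- list(inputs = cfg$inputs, thresholds = unclass(cfg$thresholds),
              filter = unclass(cfg$filter), survival = cfg$survival,
              correlation_samples = cfg$correlation_samples,
              seed = cfg$seed, outdir = cfg$outdir)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full prioritization pipeline
#'
#' Stages, in order: normalization, splicing and stemness scores, moderated
#' differential expression, score correlations, candidate selection,
#' per-candidate prognostic calls, clinical associations, the splice-event
#' pipeline (when event inputs are configured) and drug association (when
#' an IC50 input is configured). Every stage writes its TSV under
#' `outdir`, and a JSON run summary plus a plain-text log record counts,
#' the seed and every design-decision setting in effect. Deterministic for
#' a fixed config and inputs.
#'
#' @param cfg a `RunConfig` from [validate_config()].
#' @return the run summary list, invisibly; files under `cfg$outdir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  stage <- function(name, expr) {
    logf("[stage] %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  logf("seed=%d correlation_samples=%s", cfg$seed, cfg$correlation_samples)
  logf("rule1 interpretation: group-mean total junction count")
  logf("rule2 interpretation: cross-sample mean PSI")
  logf("rule5 interpretation: TPM bound met in >= 1 group")

  expr_tpm <- stage("read_inputs", read_expression(cfg$inputs$expression, "tpm"))
  samples <- read_sample_table(cfg$inputs$samples)
  factors <- read_gene_set(cfg$inputs$factors, name = "splicing_factors")
  weights <- read_weights(cfg$inputs$weights)
  if (!setequal(samples$sample_id, sample_ids_of(expr_tpm)))
    stop("sample table and expression matrix disagree on samples")

  expr <- stage("normalize", normalize_expression(expr_tpm))
  splice_s <- stage("splicing_score", splicing_score(expr, factors))
  stem_s <- stage("stemness_index", stemness_index(expr, weights))
  score_df <- data.frame(sample_id = sample_ids_of(expr),
                         splicing_score = as.numeric(splice_s[sample_ids_of(expr)]),
                         stemness_index = as.numeric(stem_s[sample_ids_of(expr)]))
  utils::write.table(score_df, file.path(cfg$outdir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- stats::setNames(samples$tissue, samples$sample_id)
  de <- stage("moderated_de",
              moderated_de(expr, groups[sample_ids_of(expr)]))
  utils::write.table(de, file.path(cfg$outdir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  restrict <- if (cfg$correlation_samples == "tumor")
    samples$sample_id[samples$tissue == "tumor"] else NULL
  c_stem <- stage("correlate_stemness",
                  correlate_with_score(expr, stem_s, restrict_to = restrict))
  c_splice <- stage("correlate_splicing",
                    correlate_with_score(expr, splice_s, restrict_to = restrict))

  # callers supply the lncRNA universe; the screen is only meaningful there
  if (!is.null(cfg$inputs$lnc_universe)) {
    uni <- read_gene_set(cfg$inputs$lnc_universe, name = "lnc_universe")$members
    uni <- intersect(uni, de$gene_id)
    de_u <- de[de$gene_id %in% uni, ]
    c_stem_u <- c_stem[c_stem$gene_id %in% uni, ]
    c_splice_u <- c_splice[c_splice$gene_id %in% uni, ]
  } else {
    de_u <- de; c_stem_u <- c_stem; c_splice_u <- c_splice
  }
  cand <- stage("select_candidates",
                select_candidates(de_u, c_stem_u, c_splice_u, cfg$thresholds))
  write_screen_output(cand, file.path(cfg$outdir, "candidates.tsv"),
                      file.path(cfg$outdir, "screen_summary.json"))

  summary <- list(seed = cfg$seed,
                  n_samples = ncol(expr$values), n_genes = nrow(expr$values),
                  n_up = attr(cand, "n_up"), n_down = attr(cand, "n_down"),
                  thresholds = unclass(cfg$thresholds))

  # prognostic calls for the selected candidates (tumor samples)
  if (all(c("surv_time", "surv_event") %in% names(samples)) &&
      any(!is.na(samples$surv_time)) && nrow(cand) > 0) {
    sv <- cfg$survival
    calls <- stage("prognostic_calls", lapply(cand$gene_id, function(gid) {
      pc <- prognostic_call(expr$values[gid, ], samples, alpha = sv$alpha,
                            alpha1 = sv$alpha1, n_perm = sv$n_perm,
                            seed = cfg$seed)
      data.frame(gene_id = gid, cutoff = pc$cutoff, n_high = pc$n_high,
                 n_low = pc$n_low, logrank_p = pc$logrank_p,
                 two_stage_p = pc$two_stage_p,
                 stage_used = ifelse(is.na(pc$stage_used), NA, pc$stage_used),
                 call = pc$call, stringsAsFactors = FALSE)
    }))
    calls <- do.call(rbind, calls)
    utils::write.table(calls, file.path(cfg$outdir, "survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_prognostic <- sum(calls$call != "NS")
  }

  # clinical association of candidate expression with non-survival covariates
  covars <- setdiff(names(samples),
                    c("sample_id", "tissue", "surv_time", "surv_event"))
  if (length(covars) && nrow(cand) > 0) {
    tum <- samples$sample_id[samples$tissue == "tumor"]
    rows <- list()
    for (gid in cand$gene_id) for (cv in covars) {
      res <- tryCatch(
        clinical_association(expr$values[gid, tum],
                             samples[[cv]][match(tum, samples$sample_id)]),
        error = function(e) NULL)
      if (!is.null(res))
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = gid, covariate = cv, method = res$method,
          statistic = res$statistic, p = res$p, stringsAsFactors = FALSE)
    }
    if (length(rows))
      utils::write.table(do.call(rbind, rows),
                         file.path(cfg$outdir, "clinical.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # splice-event pipeline
  if (!is.null(cfg$inputs$events)) {
    tab <- stage("read_events", read_event_table(cfg$inputs$events))
    gr_df <- utils::read.delim(cfg$inputs$event_groups, sep = "\t",
                               stringsAsFactors = FALSE)
    egroups <- stats::setNames(gr_df$group, gr_df$sample_id)
    tests <- stage("bb_lrt", bb_lrt(tab, egroups))
    filt <- stage("filter_events", filter_events(tests, tab, egroups,
                                                 cfg$filter))
    utils::write.table(filt$kept, file.path(cfg$outdir, "splice_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(filt$kept) > 0) {
      comp <- event_composition(filt$kept)
      dirs <- direction_split(filt$kept)
      summary$splice <- list(n_tested = sum(!is.na(tests$p)),
                             n_pass = nrow(filt$kept),
                             per_rule_attrition = as.list(filt$attrition),
                             composition = as.list(comp$proportions),
                             n_up = dirs$n_up, n_down = dirs$n_down)
    } else {
      summary$splice <- list(n_tested = sum(!is.na(tests$p)), n_pass = 0,
                             per_rule_attrition = as.list(filt$attrition))
    }
  }

  # drug association against the splicing-score axis
  if (!is.null(cfg$inputs$ic50)) {
    df <- utils::read.delim(cfg$inputs$ic50, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    ic50 <- as.matrix(df[-1])
    rownames(ic50) <- df[[1]]
    tum <- samples$sample_id[samples$tissue == "tumor"]
    axis <- splice_s[intersect(colnames(ic50), tum)]
    strat <- stratify_by_mean(axis)
    dr <- stage("drug_association", drug_association(ic50, axis, strat))
    utils::write.table(dr, file.path(cfg$outdir, "drugs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$drugs <- list(
      n_reduced = sum(dr$class == "reduced_sensitivity"),
      n_enhanced = sum(dr$class == "enhanced_sensitivity"),
      n_no_call = sum(dr$class == "no_call"))
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done")
  invisible(summary)
}
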