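#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator: cohort sizes, gene-universe layout,
#' the latent-malignancy-factor loadings, planted differential-expression
#' shifts, survival hazard, splice-event structure and drug-response
#' structure. Defaults define the frozen strong-effect reference cohort
#' used by the recovery tests.
#'
#' @param n_tumor,n_normal sample counts per tissue.
#' @param n_genes total gene-universe size (must hold all special genes).
#' @param n_factors splicing-factor set size (default 167).
#' @param n_signature stemness-signature size.
#' @param n_planted_up,n_planted_down,n_null_lnc planted concordant
#'   lncRNAs (up / down) and null lncRNAs.
#' @param loading_strength target correlation of factor-loaded genes with
#'   the latent malignancy factor, in `[0, 1)`.
#' @param latent_shift shift of the latent factor in tumors (latent units).
#' @param de_shift log2 mean shift of planted lncRNAs in tumors.
#' @param noise_sd per-gene log2 noise standard deviation.
#' @param surv_beta log-hazard per standardized unit of the survival-linked
#'   lncRNA's expression.
#' @param censor_rate target fraction of censored tumor samples, `[0, 1)`.
#' @param n_events_null,n_events_planted splice events without / with a
#'   planted group difference.
#' @param n_rep replicates per group in the splice-event tables.
#' @param planted_dpsi planted |delta PSI| for affected events.
#' @param bb_dispersion beta-binomial dispersion of inclusion counts.
#' @param depth_mean mean Poisson junction depth per event and sample.
#' @param n_drugs_pos,n_drugs_neg,n_drugs_null drugs whose IC50 tracks the
#'   axis score positively / negatively / not at all.
#' @param drug_effect slope of IC50 on the (standardized) axis score.
#' @param drug_noise_sd IC50 noise standard deviation.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return validated list of parameters, class `SimConfig`.
#' @export
sim_config <- function(n_tumor = 60, n_normal = 30, n_genes = 1000,
                       n_factors = 167, n_signature = 50,
                       n_planted_up = 23, n_planted_down = 5,
                       n_null_lnc = 100,
                       loading_strength = 0.9, latent_shift = 1.5,
                       de_shift = 2, noise_sd = 1,
                       surv_beta = 1.4, censor_rate = 0.3,
                       n_events_null = 800, n_events_planted = 200,
                       n_rep = 5, planted_dpsi = 0.2,
                       bb_dispersion = 0.02, depth_mean = 100,
                       n_drugs_pos = 10, n_drugs_neg = 10, n_drugs_null = 30,
                       drug_effect = 1, drug_noise_sd = 0.6,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_tumor >= 2, n_normal >= 2, n_genes >= 1, n_factors >= 1,
              n_signature >= 3, n_planted_up >= 0, n_planted_down >= 0,
              n_null_lnc >= 0, noise_sd > 0, depth_mean > 0, n_rep >= 2,
              bb_dispersion >= 0)
    if (loading_strength < 0 || loading_strength >= 1)
      stop("loading_strength must lie in [0, 1)")
    if (censor_rate < 0 || censor_rate >= 1)
      stop("censor_rate must lie in [0, 1)")
    if (planted_dpsi < 0 || planted_dpsi > 1)
      stop("planted_dpsi must lie in [0, 1]")
    n_special <- n_factors + n_signature + n_planted_up + n_planted_down +
      n_null_lnc
    if (n_special > n_genes)
      stop("gene universe too small for the configured special genes")
  })
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "SimConfig")
}

# Gene-id layout shared by generator and truth table.
sim_gene_ids <- function(cfg) {
  list(factors = sprintf("SF%03d", seq_len(cfg$n_factors)),
       signature = sprintf("SIG%03d", seq_len(cfg$n_signature)),
       lnc_up = if (cfg$n_planted_up) sprintf("LNCUP%03d", seq_len(cfg$n_planted_up)) else character(0),
       lnc_down = if (cfg$n_planted_down) sprintf("LNCDN%03d", seq_len(cfg$n_planted_down)) else character(0),
       lnc_null = if (cfg$n_null_lnc) sprintf("LNCNULL%03d", seq_len(cfg$n_null_lnc)) else character(0))
}

#' Generate a synthetic tumor/normal expression cohort
#'
#' A latent malignancy factor (standard normal per sample, shifted by
#' `latent_shift` in tumors) drives splicing factors, stemness-signature
#' genes (loading sign matching each gene's signature weight) and planted
#' lncRNAs; planted lncRNAs additionally carry a `de_shift` log2 shift in
#' tumors (mirrored for the down set). Null lncRNAs and background genes
#' are independent noise. Values are generated in log2 space around
#' per-gene baselines and back-transformed to TPM via `2^x - 1.01`,
#' clipped at 0. Tumor samples get exponential survival times whose
#' log-hazard is `surv_beta` per standardized unit of the first planted
#' up-lncRNA, with uniform censoring calibrated to `censor_rate`, plus an
#' ordinal stage (noisy tertiles of the latent factor) and a null binary
#' `gender` covariate.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (tpm-space `ExpressionMatrix`), `samples`
#'   (`SampleTable`), `factors` (`GeneSet`), `weights`
#'   (`SignatureWeights`), `truth` (data.frame id / role / effect), and
#'   `latent` (the per-sample latent factor, for diagnostics).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old), add = TRUE)

  n <- cfg$n_tumor + cfg$n_normal
  sample_id <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                 sprintf("N%03d", seq_len(cfg$n_normal)))
  tissue <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
  m <- stats::rnorm(n) + ifelse(tissue == "tumor", cfg$latent_shift, 0)

  ids <- sim_gene_ids(cfg)
  n_special <- length(unlist(ids))
  bg <- if (cfg$n_genes > n_special)
    sprintf("BG%04d", seq_len(cfg$n_genes - n_special)) else character(0)
  genes <- c(unlist(ids, use.names = FALSE), bg)

  # loading coefficient giving correlation = loading_strength against the
  # within-group latent factor (unit variance) at noise sd `noise_sd`
  b <- cfg$loading_strength * cfg$noise_sd /
    sqrt(1 - cfg$loading_strength^2)

  w <- stats::rnorm(cfg$n_signature)
  names(w) <- ids$signature

  base <- stats::runif(length(genes), 3, 8)
  names(base) <- genes
  x <- matrix(stats::rnorm(length(genes) * n, sd = cfg$noise_sd),
              nrow = length(genes), dimnames = list(genes, sample_id))
  x <- x + base
  load_of <- stats::setNames(numeric(length(genes)), genes)
  load_of[ids$factors] <- b
  load_of[ids$signature] <- b * sign(w[ids$signature])
  load_of[ids$lnc_up] <- b
  load_of[ids$lnc_down] <- -b
  x <- x + outer(load_of, m)
  is_tum <- tissue == "tumor"
  x[ids$lnc_up, is_tum] <- x[ids$lnc_up, is_tum] + cfg$de_shift
  x[ids$lnc_down, is_tum] <- x[ids$lnc_down, is_tum] - cfg$de_shift

  tpm <- pmax(2^x - 1.01, 0)
  expr <- expression_matrix(tpm, space = "tpm")

  # survival: tumors only, hazard tied to the first planted up-lncRNA
  surv_time <- surv_event <- rep(NA_real_, n)
  surv_gene <- if (cfg$n_planted_up > 0) ids$lnc_up[1] else NA_character_
  if (!is.na(surv_gene)) {
    z <- x[surv_gene, is_tum]
    z <- (z - mean(z)) / stats::sd(z)
    rate <- exp(cfg$surv_beta * z) / 1000   # baseline mean 1000 days
    tt <- stats::rexp(cfg$n_tumor, rate = rate)
    ev <- rep(1, cfg$n_tumor)
    if (cfg$censor_rate > 0) {
      f <- function(cmax) mean(pmin(tt / cmax, 1)) - cfg$censor_rate
      cmax <- stats::uniroot(f, c(min(tt) * 1e-3, max(tt) * 1e3))$root
      cc <- stats::runif(cfg$n_tumor, 0, cmax)
      ev <- as.numeric(tt <= cc)
      tt <- pmin(tt, cc)
    }
    surv_time[is_tum] <- tt
    surv_event[is_tum] <- ev
  }

  stage <- rep(NA_character_, n)
  noisy <- m[is_tum] + stats::rnorm(cfg$n_tumor, sd = 0.5)
  stage[is_tum] <- as.character(cut(noisy,
    stats::quantile(noisy, c(0, 1/3, 2/3, 1)),
    labels = c("I", "II", "III"), include.lowest = TRUE))

  samples <- validate_sample_table(data.frame(
    sample_id = sample_id, tissue = tissue, stage = stage,
    surv_time = surv_time, surv_event = surv_event,
    gender = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE))

  truth_rows <- function(id, role, effect)
    data.frame(id = id, role = rep_len(role, length(id)),
               effect = rep_len(effect, length(id)),
               stringsAsFactors = FALSE)
  truth <- rbind(
    truth_rows(ids$lnc_up, "lncRNA_up", cfg$de_shift),
    truth_rows(ids$lnc_down, "lncRNA_down", -cfg$de_shift),
    truth_rows(ids$lnc_null, "lncRNA_null", 0))
  if (!is.na(surv_gene))
    truth <- rbind(truth, data.frame(id = surv_gene, role = "survival_link",
                                     effect = cfg$surv_beta))

  list(expr = expr, samples = samples,
       factors = gene_set(ids$factors, name = "splicing_factors"),
       weights = signature_weights(w), truth = truth, latent = m)
}

#' Generate synthetic splice-event junction-count tables
#'
#' Two groups of `n_rep` replicates. Each event has a base PSI drawn
#' uniform on (0.2, 0.8); planted events shift group 1 by
#' `+/- planted_dpsi` (alternating sign), clipped to `[0.05, 0.95]`.
#' Per-sample totals are Poisson(`depth_mean`); inclusion counts are
#' beta-binomial with dispersion `bb_dispersion`. Event classes follow a
#' configurable composition (default SE 58.01%, RI 13.38%, MXE 10.23%,
#' A3SS 9.93%, A5SS 8.45%). Planted-event genes get group TPM >= 1.
#'
#' @param cfg a [sim_config()].
#' @param composition named class proportions, summing to 1.
#' @return list with `table` (a `SpliceEventTable` with groups `g1`,`g2`),
#'   `groups` (named sample -> group vector), `truth` (per-event role and
#'   true delta PSI).
#' @export
generate_events <- function(cfg,
                            composition = c(SE = 0.5801, RI = 0.1338,
                                            MXE = 0.1023, A3SS = 0.0993,
                                            A5SS = 0.0845)) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (abs(sum(composition) - 1) > 1e-6)
    stop("event-class composition must sum to 1")
  old <- local_seed(cfg$seed + 1L)
  on.exit(restore_seed(old), add = TRUE)

  n_ev <- cfg$n_events_null + cfg$n_events_planted
  if (n_ev == 0) stop("no events configured")
  planted <- rep(c(TRUE, FALSE), c(cfg$n_events_planted, cfg$n_events_null))
  event_id <- sprintf("EV%05d", seq_len(n_ev))
  gene_id <- sprintf("EVG%05d", seq_len(n_ev))
  event_class <- sample(names(composition), n_ev, replace = TRUE,
                        prob = composition)
  samples <- c(sprintf("G1R%02d", seq_len(cfg$n_rep)),
               sprintf("G2R%02d", seq_len(cfg$n_rep)))
  groups <- stats::setNames(rep(c("g1", "g2"), each = cfg$n_rep), samples)

  base_psi <- stats::runif(n_ev, 0.2, 0.8)
  shift_sign <- rep_len(c(1, -1), n_ev)
  psi_g1 <- ifelse(planted,
                   pmin(0.95, pmax(0.05, base_psi + shift_sign * cfg$planted_dpsi)),
                   base_psi)
  psi_g2 <- base_psi

  rbb <- function(n_draw, size, mu, rho) {
    if (rho <= 0) return(stats::rbinom(n_draw, size, mu))
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    stats::rbinom(n_draw, size, stats::rbeta(n_draw, a, b))
  }
  inc <- skip <- matrix(0L, n_ev, 2 * cfg$n_rep,
                        dimnames = list(event_id, samples))
  for (i in seq_len(n_ev)) {
    tot <- stats::rpois(2 * cfg$n_rep, cfg$depth_mean)
    mu <- ifelse(groups == "g1", psi_g1[i], psi_g2[i])
    k <- rbb(2 * cfg$n_rep, tot, mu, cfg$bb_dispersion)
    inc[i, ] <- as.integer(k)
    skip[i, ] <- as.integer(tot - k)
  }
  tpm <- cbind(g1 = stats::runif(n_ev, 0.2, 50),
               g2 = stats::runif(n_ev, 0.2, 50))
  tpm[planted, ] <- pmax(tpm[planted, ], 1)
  rownames(tpm) <- event_id

  # unit effective lengths so the planted PSI equals the count-level
  # inclusion fraction exactly
  events <- data.frame(event_id = event_id, gene_id = gene_id,
                       event_class = event_class,
                       inclusion_len = 1L, skipping_len = 1L,
                       stringsAsFactors = FALSE)
  truth <- data.frame(id = event_id,
                      role = ifelse(planted, "event_planted", "event_null"),
                      effect = psi_g1 - psi_g2, stringsAsFactors = FALSE)
  list(table = splice_event_table(events, inc, skip, tpm),
       groups = groups, truth = truth)
}

#' Generate a synthetic drug-sensitivity (IC50) matrix
#'
#' Positive drugs have IC50 rising with the axis score (slope
#' `drug_effect` on the standardized score), negative drugs mirrored,
#' null drugs pure noise; all with Gaussian noise `drug_noise_sd` around a
#' per-drug baseline.
#'
#' @param cfg a [sim_config()].
#' @param axis_scores named numeric vector of per-sample axis scores.
#' @return list with `ic50` (drugs x samples matrix) and `truth`.
#' @export
generate_ic50 <- function(cfg, axis_scores) {
  stopifnot(inherits(cfg, "SimConfig"))
  s <- drop_score_attrs(axis_scores)
  if (stats::sd(s) == 0) stop("axis scores are constant")
  z <- (s - mean(s)) / stats::sd(s)
  old <- local_seed(cfg$seed + 2L)
  on.exit(restore_seed(old), add = TRUE)
  drugs <- c(if (cfg$n_drugs_pos) sprintf("DPOS%02d", seq_len(cfg$n_drugs_pos)),
             if (cfg$n_drugs_neg) sprintf("DNEG%02d", seq_len(cfg$n_drugs_neg)),
             if (cfg$n_drugs_null) sprintf("DNULL%02d", seq_len(cfg$n_drugs_null)))
  role <- rep(c("drug_pos", "drug_neg", "drug_null"),
              c(cfg$n_drugs_pos, cfg$n_drugs_neg, cfg$n_drugs_null))
  slope <- ifelse(role == "drug_pos", cfg$drug_effect,
                  ifelse(role == "drug_neg", -cfg$drug_effect, 0))
  ic50 <- matrix(NA_real_, length(drugs), length(z),
                 dimnames = list(drugs, names(z)))
  for (i in seq_along(drugs)) {
    ic50[i, ] <- stats::runif(1, 1, 5) + slope[i] * z +
      stats::rnorm(length(z), sd = cfg$drug_noise_sd)
  }
  list(ic50 = ic50,
       truth = data.frame(id = drugs, role = role, effect = slope,
                          stringsAsFactors = FALSE))
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits `expression.tsv`, `samples.tsv`, `factors.txt`, `weights.tsv`,
#' `events.tsv`, `event_groups.tsv`, `ic50.tsv`, `truth.tsv` and
#' `sim_config.yaml`, the on-disk bundle the pipeline consumes.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg)
  ev <- generate_events(cfg)
  scores <- splicing_score(normalize_expression(cohort$expr), cohort$factors)
  drugs <- generate_ic50(cfg, scores)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  writeLines(cohort$factors$members, file.path(dir, "factors.txt"))
  ids <- sim_gene_ids(cfg)
  writeLines(c(ids$lnc_up, ids$lnc_down, ids$lnc_null),
             file.path(dir, "lnc_universe.txt"))
  write_weights(cohort$weights, file.path(dir, "weights.tsv"))
  write_event_table(ev$table, file.path(dir, "events.tsv"))
  utils::write.table(
    data.frame(sample_id = names(ev$groups), group = ev$groups),
    file.path(dir, "event_groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(drug = rownames(drugs$ic50), drugs$ic50, check.names = FALSE),
    file.path(dir, "ic50.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- rbind(cohort$truth, ev$truth, drugs$truth)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
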