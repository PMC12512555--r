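test_that("PSI is the length-normalized inclusion fraction", {
  expect_equal(compute_psi(10, 10, 2, 1), 1/3)
  expect_equal(compute_psi(5, 0), 1)
  expect_true(is.na(compute_psi(0, 0)))
  expect_equal(compute_psi(c(10, 5, 0), c(10, 0, 0), 2, 1),
               c(1/3, 1, NA))
  expect_error(compute_psi(-1, 5), ">= 0")
  expect_error(compute_psi(1, 5, inc_len = 0), ">= 1")
  tab <- make_event_table(inc1 = c(10, 10), skip1 = c(10, 10),
                          inc2 = c(2, 2), skip2 = c(18, 18),
                          inc_len = 2, skip_len = 1)
  psi <- psi_matrix(tab)
  expect_equal(unname(psi["ev1", "A1"]), 1/3)
  expect_equal(unname(psi["ev1", "B1"]), (2/2) / (2/2 + 18))
})

test_that("identical replicate groups give a null likelihood-ratio test", {
  tab <- make_event_table(inc1 = c(12, 15, 11), skip1 = c(8, 5, 9),
                          inc2 = c(12, 15, 11), skip2 = c(8, 5, 9))
  res <- bb_lrt(tab, event_groups_for(tab), calibrate = FALSE)
  expect_lt(res$lrt_stat[1], 1e-6)
  expect_gt(res$p[1], 0.999)
  expect_equal(res$delta_psi[1], 0)
})

test_that("rho = 0 statistic matches the grid-search binomial LRT oracle", {
  cases <- list(
    list(inc1 = c(30, 28, 35), skip1 = c(70, 72, 65),
         inc2 = c(45, 50, 40), skip2 = c(55, 50, 60)),
    list(inc1 = c(5, 8), skip1 = c(15, 12),
         inc2 = c(9, 7), skip2 = c(11, 13)))
  for (cs in cases) {
    tab <- do.call(make_event_table, cs)
    res <- bb_lrt(tab, event_groups_for(tab), rho_fixed = 0,
                  calibrate = FALSE)
    k <- tab$inc[1, ]; n <- k + tab$skip[1, ]
    g <- ifelse(grepl("^A", names(k)), 1, 2)
    oracle <- binom_lrt_grid_oracle(k, n, g)
    expect_equal(res$lrt_stat[1], oracle, tolerance = 1e-6)
  }
})

test_that("swapping group labels negates delta PSI and preserves p", {
  set.seed(61)
  tab <- make_event_table(inc1 = c(40, 35, 42, 38), skip1 = c(60, 65, 58, 62),
                          inc2 = c(55, 60, 52, 58), skip2 = c(45, 40, 48, 42))
  g <- event_groups_for(tab)
  g_swap <- stats::setNames(ifelse(g == "g1", "g2", "g1"), names(g))
  # with swapped labels sort(unique()) still maps A->g2 now, so group 1
  # becomes the B samples
  r1 <- bb_lrt(tab, g, calibrate = FALSE)
  r2 <- bb_lrt(tab, g_swap, calibrate = FALSE)
  expect_equal(r2$delta_psi[1], -r1$delta_psi[1])
  expect_equal(r2$p[1], r1$p[1], tolerance = 1e-8)
})

test_that("events with too few usable replicates are skipped with a flag", {
  tab <- make_event_table(inc1 = c(10, 0), skip1 = c(5, 0),
                          inc2 = c(8, 9), skip2 = c(7, 6))
  res <- bb_lrt(tab, event_groups_for(tab))
  expect_identical(res$flag[1], "too_few_replicates")
  expect_true(is.na(res$p[1]))
})

test_that("the five filter rules drop events in printed order", {
  R <- 4
  mk <- function(psi1, psi2, depth, tpm1, tpm2) {
    list(inc1 = round(depth * psi1) + integer(R),
         skip1 = round(depth * (1 - psi1)) + integer(R),
         inc2 = round(depth * psi2) + integer(R),
         skip2 = round(depth * (1 - psi2)) + integer(R),
         tpm = c(tpm1, tpm2))
  }
  specs <- list(
    pass    = mk(0.30, 0.60, 100, 5, 5),
    lowcnt  = mk(0.30, 0.60, 3, 5, 5),       # rule 1: mean total < 10
    extreme = mk(0.97, 0.97, 100, 5, 5),     # rule 2: mean PSI > 0.95
    nullpsi = mk(0.50, 0.50, 100, 5, 5),     # rule 3: not significant
    tiny    = mk(0.50, 0.54, 2000, 5, 5),    # rule 4: |dPSI| 0.04 (if sig)
    lowtpm  = mk(0.30, 0.60, 100, 0.2, 0.5)) # rule 5: TPM < 1 both groups
  n_ev <- length(specs)
  inc <- do.call(rbind, lapply(specs, function(s) c(s$inc1, s$inc2)))
  skp <- do.call(rbind, lapply(specs, function(s)
    c(s$skip1, s$skip2)))
  samples <- c(sprintf("A%d", 1:R), sprintf("B%d", 1:R))
  dimnames(inc) <- dimnames(skp) <- list(names(specs), samples)
  storage.mode(inc) <- "integer"; storage.mode(skp) <- "integer"
  tpm <- do.call(rbind, lapply(specs, function(s) s$tpm))
  dimnames(tpm) <- list(names(specs), c("g1", "g2"))
  events <- data.frame(event_id = names(specs),
                       gene_id = paste0("gene_", names(specs)),
                       event_class = c("SE", "RI", "SE", "MXE", "SE", "A3SS"),
                       inclusion_len = 1L, skipping_len = 1L)
  tab <- splice_event_table(events, inc, skp, tpm)
  g <- event_groups_for(tab)
  tests <- bb_lrt(tab, g)
  filt <- filter_events(tests, tab, g)
  expect_identical(filt$kept$event_id, "pass")
  att <- filt$attrition
  expect_identical(unname(att["rule1_count"]), 1L)
  expect_identical(unname(att["rule2_psi_range"]), 1L)
  expect_gte(att["rule3_fdr"], 1)            # nullpsi (tiny may die here too)
  expect_identical(
    unname(att["rule1_count"] + att["rule2_psi_range"] + att["rule3_fdr"] +
             att["rule4_dpsi"] + att["rule5_tpm"] + att["untested"]),
    n_ev - 1L)
  # re-filtering the kept set is idempotent
  tests_kept <- tests[tests$event_id %in% filt$kept$event_id, ]
  keep_ids <- filt$kept$event_id
  tab_kept <- splice_event_table(
    events[events$event_id %in% keep_ids, ],
    inc[keep_ids, , drop = FALSE], skp[keep_ids, , drop = FALSE],
    tpm[keep_ids, , drop = FALSE])
  filt2 <- filter_events(tests_kept, tab_kept, g)
  expect_identical(filt2$kept$event_id, filt$kept$event_id)
})

test_that("filtering is antitone under random threshold tightening", {
  set.seed(67)
  cfg <- sim_config(n_events_null = 60, n_events_planted = 40,
                    planted_dpsi = 0.25, seed = 5)
  ev <- generate_events(cfg)
  tests <- bb_lrt(ev$table, ev$groups)
  base_fc <- filter_criteria()
  base <- filter_events(tests, ev$table, ev$groups, base_fc)
  for (i in 1:40) {
    fc <- filter_criteria(
      count_min = base_fc$count_min + stats::runif(1, 0, 60),
      psi_lo = stats::runif(1, base_fc$psi_lo, 0.3),
      psi_hi = stats::runif(1, 0.7, base_fc$psi_hi),
      fdr_max = base_fc$fdr_max * stats::runif(1, 0.05, 1),
      dpsi_min = base_fc$dpsi_min + stats::runif(1, 0, 0.2),
      tpm_min = base_fc$tpm_min + stats::runif(1, 0, 5))
    tight <- filter_events(tests, ev$table, ev$groups, fc)
    expect_true(all(tight$kept$event_id %in% base$kept$event_id))
  }
  expect_error(filter_criteria(psi_lo = 0.9, psi_hi = 0.1), "psi_lo")
})

test_that("event composition and direction split partition the filtered set", {
  comp <- event_composition(c("SE", "SE", "RI", "MXE"))
  expect_equal(unname(comp$proportions),
               c(0.5, 0.25, 0.25, 0, 0))
  expect_equal(sum(comp$proportions), 1, tolerance = 1e-12)
  expect_equal(sum(event_composition(rep("SE", 10))$proportions[1]), 1)
  expect_error(event_composition(character(0)), "empty")
  expect_error(event_composition("XX"), "unknown")

  kept <- data.frame(delta_psi = c(0.1, 0.2, -0.3))
  ds <- direction_split(kept)
  expect_identical(ds$n_up, 2L)
  expect_identical(ds$n_down, 1L)
  expect_identical(ds$n_up + ds$n_down, ds$n_total)
})
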