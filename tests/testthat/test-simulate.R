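small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_tumor = 20, n_normal = 15, n_genes = 120, n_factors = 25,
         n_signature = 15, n_planted_up = 4, n_planted_down = 2,
         n_null_lnc = 20, n_events_null = 30, n_events_planted = 10,
         n_drugs_pos = 2, n_drugs_neg = 2, n_drugs_null = 5, seed = seed),
    list(...))
  do.call(sim_config, args)
}

test_that("generation is deterministic in the seed", {
  a <- generate_cohort(small_cfg(seed = 4))
  b <- generate_cohort(small_cfg(seed = 4))
  c <- generate_cohort(small_cfg(seed = 5))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$samples$surv_time, b$samples$surv_time)
  expect_false(identical(a$expr$values, c$expr$values))
  e1 <- generate_events(small_cfg(seed = 4))
  e2 <- generate_events(small_cfg(seed = 4))
  expect_identical(e1$table$inc, e2$table$inc)
})

test_that("generated data satisfy the container invariants", {
  co <- generate_cohort(small_cfg(seed = 6))
  expect_true(all(co$expr$values >= 0))
  expect_identical(co$expr$space, "tpm")
  st <- co$samples
  tum <- st$tissue == "tumor"
  expect_true(all(st$surv_time[tum] > 0))
  expect_true(all(st$surv_event[tum] %in% c(0, 1)))
  expect_true(all(is.na(st$surv_time[!tum])))
  # truth ids resolve in the generated data
  expect_true(all(co$truth$id %in% rownames(co$expr$values)))
  ev <- generate_events(small_cfg(seed = 6))
  expect_true(all(ev$truth$id %in% ev$table$events$event_id))
  expect_true(all(ev$table$inc >= 0))
  # planted-event genes satisfy the TPM floor
  planted <- ev$truth$role == "event_planted"
  expect_true(all(ev$table$tpm[planted, ] >= 1))
})

test_that("the default event-class composition matches its target mix", {
  cfg <- sim_config(n_events_null = 4000, n_events_planted = 0, seed = 8)
  ev <- generate_events(cfg)
  comp <- event_composition(ev$table$events$event_class)
  target <- c(SE = 0.5801, RI = 0.1338, MXE = 0.1023, A3SS = 0.0993,
              A5SS = 0.0845)
  expect_equal(comp$proportions, target, tolerance = 0.05)
  expect_error(generate_events(small_cfg(), composition = c(SE = 0.4)),
               "sum to 1")
})

test_that("a fully null cohort yields no screen candidates beyond chance", {
  cfg <- small_cfg(seed = 9, n_genes = 400, n_null_lnc = 100,
                   n_planted_up = 0, n_planted_down = 0,
                   loading_strength = 0, latent_shift = 0, de_shift = 0,
                   surv_beta = 0)
  co <- generate_cohort(cfg)
  expr <- normalize_expression(co$expr)
  de <- moderated_de(expr, co$samples$tissue)
  ss <- splicing_score(expr, co$factors)
  si <- stemness_index(expr, co$weights)
  tum <- co$samples$sample_id[co$samples$tissue == "tumor"]
  cs <- correlate_with_score(expr, si, restrict_to = tum)
  cp <- correlate_with_score(expr, ss, restrict_to = tum)
  uni <- co$truth$id
  cand <- select_candidates(de[de$gene_id %in% uni, ],
                            cs[cs$gene_id %in% uni, ],
                            cp[cp$gene_id %in% uni, ])
  expect_lte(nrow(cand), 2)
})

test_that("strong loadings put planted lncRNAs above the splicing threshold", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_tumor = 50, n_normal = 50, loading_strength = 0.9,
                      de_shift = 2, seed = 200 + s)
    co <- generate_cohort(cfg)
    expr <- normalize_expression(co$expr)
    ss <- splicing_score(expr, co$factors)
    r <- stats::cor(expr$values["LNCUP001", ], as.numeric(ss))
    if (r > 0.45) hits <- hits + 1
  }
  expect_gte(hits / 10, 0.95 - 1e-9)
})

test_that("null drugs are mostly no_call and IC50 structure matches truth", {
  cfg <- small_cfg(seed = 12, n_drugs_null = 40)
  co <- generate_cohort(cfg)
  ss <- splicing_score(normalize_expression(co$expr), co$factors)
  tum <- co$samples$sample_id[co$samples$tissue == "tumor"]
  dr <- generate_ic50(cfg, ss[tum])
  calls <- drug_association(dr$ic50, ss[tum], stratify_by_mean(ss[tum]))
  nulls <- dr$truth$id[dr$truth$role == "drug_null"]
  expect_gte(mean(calls$class[calls$drug %in% nulls] == "no_call"), 0.9)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_genes = 10), "too small")
  expect_error(sim_config(loading_strength = 1), "loading_strength")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
})

test_that("write_bundle emits a complete consistent input set", {
  dir <- withr::local_tempdir()
  write_bundle(small_cfg(seed = 13), dir)
  files <- c("expression.tsv", "samples.tsv", "factors.txt", "weights.tsv",
             "lnc_universe.txt", "events.tsv", "event_groups.tsv",
             "ic50.tsv", "truth.tsv", "sim_config.yaml")
  expect_true(all(file.exists(file.path(dir, files))))
  m <- read_expression(file.path(dir, "expression.tsv"), "tpm")
  st <- read_sample_table(file.path(dir, "samples.tsv"))
  expect_setequal(st$sample_id, colnames(m$values))
  tru <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_true(all(c("lncRNA_up", "event_planted", "drug_pos") %in% tru$role))
})
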