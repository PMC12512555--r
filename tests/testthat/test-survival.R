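test_that("Kaplan-Meier product-limit matches hand-computed curves", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  km2 <- km_estimate(c(1, 2, 2, 3), c(1, 0, 1, 1))
  expect_equal(km2$time, c(1, 2, 3))
  expect_equal(km2$survival, c(3/4, 1/2, 0))
  expect_warning(km0 <- km_estimate(5, 0), "no events")
  expect_equal(km_survival_at(km0, c(0, 10)), c(1, 1))
  # uncensored KM equals 1 - ECDF at event times
  set.seed(3)
  tt <- stats::rexp(40)
  km3 <- km_estimate(tt, rep(1, 40))
  expect_equal(km3$survival, 1 - stats::ecdf(tt)(km3$time))
})

test_that("log-rank test matches the survival-package oracle", {
  skip_if_not_installed("survival")
  set.seed(19)
  for (i in 1:5) {
    tA <- stats::rexp(15, 1); eA <- stats::rbinom(15, 1, 0.8)
    tB <- stats::rexp(15, 2); eB <- stats::rbinom(15, 1, 0.8)
    mine <- logrank_test(tA, eA, tB, eB)
    ref <- survival::survdiff(
      survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(1:2, each = 15))
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
  }
  # symmetry under relabeling and exact null on identical groups
  s1 <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(4, 5, 6), c(1, 1, 1))
  s2 <- logrank_test(c(4, 5, 6), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(s1$p, s2$p)
  same <- logrank_test(c(1, 2, 3), c(1, 0, 1), c(1, 2, 3), c(1, 0, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("log-rank null p-values are uniform", {
  set.seed(5)
  ps <- replicate(500, {
    logrank_test(stats::rexp(30), rep(1, 30), stats::rexp(30), rep(1, 30))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("two-stage test reduces to log-rank at alpha1 = 1 and records stage", {
  set.seed(41)
  tA <- stats::rexp(25); tB <- stats::rexp(25, 1.2)
  lr <- logrank_test(tA, rep(1, 25), tB, rep(1, 25))
  ts <- two_stage_test(tA, rep(1, 25), tB, rep(1, 25), alpha1 = 1)
  expect_identical(ts$p, lr$p)
  expect_identical(ts$stage_used, 1L)
  # strong proportional hazards fire stage 1
  set.seed(43)
  tA2 <- stats::rexp(50, 3); tB2 <- stats::rexp(50, 1)
  ts2 <- two_stage_test(tA2, rep(1, 50), tB2, rep(1, 50), n_perm = 200,
                        seed = 1)
  expect_identical(ts2$stage_used, 1L)
  expect_lt(ts2$p, 0.05)
  # permutation p has the add-one resolution and is deterministic in seed
  set.seed(47)
  tA3 <- stats::rexp(12); tB3 <- stats::rexp(12)
  ts3 <- two_stage_test(tA3, rep(1, 12), tB3, rep(1, 12), alpha1 = 0,
                        n_perm = 100, seed = 9)
  expect_identical(ts3$stage_used, 2L)
  expect_true(ts3$p >= 1 / 101 && ts3$p <= 1)
  expect_equal(ts3$p * 101, round(ts3$p * 101))
  ts3b <- two_stage_test(tA3, rep(1, 12), tB3, rep(1, 12), alpha1 = 0,
                         n_perm = 100, seed = 9)
  expect_identical(ts3$p, ts3b$p)
})

test_that("stage 2 beats the log-rank on crossing hazards", {
  pw <- function(n, r1, r2) {
    t1 <- stats::rexp(n, r1)
    ifelse(t1 <= 0.5, t1, 0.5 + stats::rexp(n, r2))
  }
  wins <- 0
  for (s in 1:15) {
    set.seed(s)
    tA <- pw(50, 2.5, 0.15); tB <- pw(50, 0.15, 2.5)
    lr <- logrank_test(tA, rep(1, 50), tB, rep(1, 50))
    ts <- two_stage_test(tA, rep(1, 50), tB, rep(1, 50), alpha1 = 0,
                         n_perm = 300, seed = s)
    if (ts$p < lr$p) wins <- wins + 1
  }
  expect_gte(wins / 15, 0.9)
})

test_that("prognostic call flags hazard-linked genes with the right direction", {
  make_surv <- function(expr, beta, seed) {
    set.seed(seed)
    n <- length(expr)
    z <- (expr - mean(expr)) / stats::sd(expr)
    tt <- stats::rexp(n, rate = exp(beta * z) / 100)
    validate_sample_table(data.frame(
      sample_id = names(expr), tissue = "tumor",
      surv_time = tt, surv_event = 1))
  }
  set.seed(53)
  expr <- stats::setNames(stats::rnorm(60, 5), sprintf("p%02d", 1:60))
  st <- make_surv(expr, beta = log(4), seed = 1)
  pc <- prognostic_call(expr, st, n_perm = 200, seed = 1)
  expect_identical(pc$call, "Poor")
  # flipping the expression sign flips the direction
  pc_flip <- prognostic_call(-expr, st, n_perm = 200, seed = 1)
  expect_identical(pc_flip$call, "Better")
  # null expression is mostly NS (combined test level ~ 0.1)
  ns <- 0
  for (s in 1:25) {
    set.seed(100 + s)
    e2 <- stats::setNames(stats::rnorm(60, 5), sprintf("p%02d", 1:60))
    st2 <- make_surv(stats::setNames(stats::rnorm(60), names(e2)), 0,
                     seed = s)
    if (prognostic_call(e2, st2, n_perm = 200, seed = s)$call == "NS")
      ns <- ns + 1
  }
  expect_gte(ns / 25, 0.8)
  # degenerate stratification yields NS with a reason
  flat <- stats::setNames(rep(2, 60), sprintf("p%02d", 1:60))
  pc_flat <- prognostic_call(flat, st)
  expect_identical(pc_flat$call, "NS")
  expect_match(pc_flat$reason, "degenerate")
})
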