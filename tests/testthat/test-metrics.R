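test_that("concordance index handles perfect order, inversion, and ties", {
  rec <- surv_records(1:3, c(1, 2, 3), c(1, 1, 1))
  expect_equal(concordance_index(rec, c(10, 20, 30)),
               list(c_index = 1, n_pairs = 3L))
  expect_equal(concordance_index(rec, c(30, 20, 10))$c_index, 0)
  # all predictions tied -> every comparable pair scores 0.5
  expect_equal(concordance_index(rec, c(5, 5, 5))$c_index, 0.5)
  # tied observed times are not comparable
  rec_t <- surv_records(1:3, c(2, 2, 5), c(1, 1, 1))
  expect_equal(concordance_index(rec_t, c(1, 2, 3))$n_pairs, 2L)
  # no comparable pairs -> explicit undefined, not 0.5
  rec_c <- surv_records(1:2, c(1, 2), c(0, 0))
  out <- concordance_index(rec_c, c(1, 2))
  expect_true(is.na(out$c_index))
  expect_identical(out$n_pairs, 0L)
})

test_that("concordance index equals the exhaustive pairwise oracle", {
  for (seed in 1:200) {
    inst <- random_instance(30, seed,
                            tie_grid = if (seed %% 3 == 0) 1:8 else NULL)
    pred <- if (seed %% 4 == 0) round(inst$pred / 100) else inst$pred
    got <- concordance_index(inst$records, pred)
    want <- oracle_cindex(inst$time, inst$event, pred)
    expect_identical(got$n_pairs, as.integer(want$n_pairs))
    expect_equal(got$c_index, want$c_index, tolerance = 1e-12)
  }
})

test_that("concordance is invariant to monotone transforms and beats noise", {
  inst <- random_instance(60, 42)
  base <- concordance_index(inst$records, inst$pred)$c_index
  expect_equal(concordance_index(inst$records, log(inst$pred))$c_index, base)
  expect_equal(concordance_index(inst$records, inst$pred^3)$c_index, base)
  # true linear predictor orders better than its random permutation
  for (seed in 1:10) {
    sim <- simulate_ph(150, beta = 1, seed = seed)
    ci_true <- concordance_index(sim$records, -sim$lp)$c_index
    set.seed(seed + 1000)
    ci_perm <- concordance_index(sim$records, -sample(sim$lp))$c_index
    expect_gt(ci_true, ci_perm)
  }
})

test_that("MAE is computed on uncensored subjects only", {
  rec <- surv_records(1:3, c(252, 400, 700), c(1, 0, 1))
  # the worked single-subject case: observed 252, predicted 251 -> 1 day
  expect_equal(mae_uncensored(rec[1, ], 251)$mae_days, 1)
  # identity predictions -> zero error
  expect_equal(mae_uncensored(rec, c(252, 999, 700))$mae_days, 0)
  # censored subjects do not influence the value
  a <- mae_uncensored(rec, c(300, 1, 800))
  b <- mae_uncensored(rec, c(300, 1e6, 800))
  expect_equal(a$mae_days, b$mae_days)
  expect_identical(a$n_uncensored, 2L)
  # mixed random instance vs filter-then-average oracle
  for (seed in 1:50) {
    inst <- random_instance(25, seed)
    expect_equal(mae_uncensored(inst$records, inst$pred)$mae_days,
                 oracle_mae(inst$time, inst$event, inst$pred))
  }
  out <- mae_uncensored(surv_records(1, 10, 0), 5)
  expect_true(is.na(out$mae_days))
})

test_that("horizon accuracy excludes subjects censored before the horizon", {
  rec <- surv_records(1:1, 800, 1)
  expect_equal(horizon_status_accuracy(rec, 900, 730)$accuracy, 1)
  # censored at 300 days: 2-year status unknowable
  rec2 <- surv_records(1:2, c(300, 800), c(0, 1))
  out <- horizon_status_accuracy(rec2, c(100, 900), 730)
  expect_identical(out$n_evaluable, 1L)
  expect_equal(out$accuracy, 1)
  out0 <- horizon_status_accuracy(surv_records(1, 100, 0), 500, 730)
  expect_true(is.na(out0$accuracy))
  for (seed in 1:50) {
    inst <- random_instance(40, seed)
    for (hz in c(730, 1825)) {
      got <- horizon_status_accuracy(inst$records, inst$pred, hz)
      want <- oracle_horizon_acc(inst$time, inst$event, inst$pred, hz)
      expect_equal(got$accuracy, want$accuracy)
      expect_identical(got$n_evaluable, as.integer(want$n))
    }
  }
})

test_that("Kaplan-Meier matches hand product-limit calculations", {
  # no censoring: empirical survival with steps 0.75, 0.5, 0.25, 0
  rec <- surv_records(1:4, c(1, 2, 3, 4), c(1, 1, 1, 1))
  km <- kaplan_meier(rec)
  expect_equal(km$survival, c(1, 0.75, 0.5, 0.25, 0))
  # censoring: S = 3/4 after t=1, 3/8 after t=3, 0 after t=4
  rec2 <- surv_records(1:4, c(1, 2, 3, 4), c(1, 0, 1, 1))
  km2 <- kaplan_meier(rec2)
  expect_equal(km2$time, c(0, 1, 3, 4))
  expect_equal(km2$survival, c(1, 0.75, 0.375, 0))
  # all censored: flat at 1
  km3 <- kaplan_meier(surv_records(1:3, c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(km3$survival == 1))
  # random instances vs the oracle
  for (seed in 1:100) {
    inst <- random_instance(20, seed,
                            tie_grid = if (seed %% 2) NULL else 1:6)
    got <- kaplan_meier(inst$records)
    want <- oracle_km(inst$time, inst$event)
    expect_equal(got$time, want$time)
    expect_equal(got$survival, want$survival, tolerance = 1e-12)
  }
})

test_that("log-rank test matches the O-E/V table oracle and is symmetric", {
  a <- surv_records(1:5, c(2, 4, 6, 8, 10), c(1, 1, 0, 1, 0))
  b <- surv_records(1:5, c(1, 3, 5, 7, 9), c(1, 0, 1, 1, 1))
  got <- log_rank_test(a, b)
  want <- oracle_logrank(a$time, a$event, b$time, b$event)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  # symmetry under label swap
  expect_equal(log_rank_test(b, a)$statistic, got$statistic,
               tolerance = 1e-10)
  # identical groups: statistic ~ 0, p ~ 1
  same <- log_rank_test(a, a)
  expect_lt(same$statistic, 1e-10)
  expect_gt(same$p_value, 0.999)
})

test_that("log-rank detects a strong hazard ratio", {
  hits <- 0
  for (seed in 1:40) {
    set.seed(seed)
    t1 <- rexp(200, 1 / 300)
    t2 <- rexp(200, 3 / 300)  # hazard ratio 3
    p <- log_rank_test(surv_records(1:200, t1, rep(1, 200)),
                       surv_records(1:200, t2, rep(1, 200)))$p_value
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("metric bundle aggregates the four metrics with counts", {
  inst <- random_instance(50, 8)
  mb <- metric_bundle(inst$records, inst$pred)
  expect_equal(mb$c_index,
               concordance_index(inst$records, inst$pred)$c_index)
  expect_equal(mb$mae_days, mae_uncensored(inst$records, inst$pred)$mae_days)
  expect_named(mb$n_eval,
               c("pairs", "uncensored", "evaluable_2yr", "evaluable_5yr"))
  tab <- metric_table(list(mb, mb))
  expect_equal(nrow(tab), 4)  # 2 folds + mean + sd
  expect_equal(as.numeric(tab$c_index[3]), mb$c_index)
  path <- tempfile(fileext = ".tsv")
  metric_table(list(mb, mb), path)
  expect_true(file.exists(path))
})
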