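test_that("partial-likelihood loss matches closed forms and the risk-set oracle", {
  # two subjects, equal hazards, one event: risk set of size 2 -> log 2
  r2 <- surv_records(c("a", "b"), c(1, 2), c(1, 0))
  expect_equal(coxnll(c(0, 0), r2), log(2))
  # singleton risk set -> 0 regardless of the risk value
  r1 <- surv_records("a", 5, 1)
  expect_equal(coxnll(3.7, r1), 0)
  # random instances (with and without ties) against brute force
  for (seed in 1:50) {
    inst <- random_instance(6, seed, tie_grid = if (seed %% 2) NULL else 1:4)
    expect_equal(coxnll(inst$h, inst$records),
                 oracle_coxnll(inst$h, inst$time, inst$event),
                 tolerance = 1e-12)
  }
})

test_that("loss handles the L2 term and rejects degenerate batches", {
  r <- surv_records(1:3, c(1, 2, 3), c(1, 1, 0))
  base <- coxnll(c(0.2, -0.1, 0), r)
  expect_equal(coxnll(c(0.2, -0.1, 0), r, l2_weight = 1e-2,
                      param_norm_sq = 4), base + 0.04)
  expect_error(coxnll(c(0, 0), surv_records(1:2, c(1, 2), c(0, 0))),
               "degenerate batch")
  expect_error(coxnll(c(0, 0, 0), r2 <- surv_records(1:2, c(1, 2), c(1, 0))),
               "not aligned")
})

test_that("loss gradient matches central finite differences", {
  for (seed in 1:10) {
    inst <- random_instance(sample(5:20, 1), seed,
                            tie_grid = if (seed %% 3 == 0) 1:5 else NULL)
    g <- coxnll_grad(inst$h, inst$records)
    h <- 1e-6
    for (i in seq_along(inst$h)) {
      hp <- inst$h; hp[i] <- hp[i] + h
      hm <- inst$h; hm[i] <- hm[i] - h
      fd <- (coxnll(hp, inst$records) - coxnll(hm, inst$records)) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("loss is invariant to adding a constant to every risk score", {
  for (seed in 1:20) {
    inst <- random_instance(12, seed)
    shifted <- coxnll(inst$h + 7.3, inst$records)
    expect_equal(shifted, coxnll(inst$h, inst$records), tolerance = 1e-10)
  }
})

test_that("fit_cph agrees with 1-D brute-force likelihood maximization", {
  sim <- simulate_ph(80, beta = 0.6, seed = 4)
  fit <- fit_cph(sim$design, sim$records)
  # golden-section maximization of the same partial likelihood
  nll_of <- function(b) oracle_coxnll(as.vector(sim$design) * b,
                                      sim$records$time, sim$records$event)
  opt <- optimize(nll_of, c(-3, 3), tol = 1e-10)
  expect_equal(unname(fit$coefficients), opt$minimum, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("fit_cph recovers planted coefficients", {
  sim <- simulate_ph(2000, beta = c(0.5, -0.3, 0.8), censor_frac = 0.3,
                     seed = 7)
  expect_gt(mean(sim$records$event == 0), 0.15)  # real censoring present
  fit <- fit_cph(sim$design, sim$records)
  expect_true(all(abs(fit$coefficients - c(0.5, -0.3, 0.8)) < 0.1))
  expect_true(all(fit$standard_errors > 0))
})

test_that("fit_cph is consistent: median bias shrinks with n", {
  bias_at <- function(n) {
    median(vapply(1:5, function(s) {
      sim <- simulate_ph(n, beta = 0.5, censor_frac = 0.3, seed = 100 + s)
      abs(unname(fit_cph(sim$design, sim$records)$coefficients) - 0.5)
    }, 1))
  }
  b <- c(bias_at(200), bias_at(1000), bias_at(5000))
  expect_true(b[1] > b[2] && b[2] > b[3])
})

test_that("fit_cph flags singular designs with the offending column", {
  sim <- simulate_ph(50, beta = c(0.5, 0), seed = 1)
  bad <- cbind(sim$design, dup = sim$design[, 1])
  expect_error(fit_cph(bad, sim$records), "dup")
  zero <- cbind(sim$design, z = 0)
  expect_error(fit_cph(zero, sim$records), "constant zero")
})

test_that("fit_cph reports non-convergence without erroring", {
  sim <- simulate_ph(200, beta = 1, seed = 2)
  fit <- fit_cph(sim$design, sim$records, max_iter = 1)
  expect_false(fit$converged)
})

test_that("Breslow baseline matches hand-enumerated risk sets", {
  # uniform hazards: first increment is 1/n
  n <- 7
  rec <- surv_records(1:n, c(2, 4, 5, 6, 8, 9, 10), c(1, 0, 1, 0, 0, 1, 0))
  bh <- breslow_baseline(rep(0, n), rec)
  expect_equal(bh$cumulative_hazard[1], 1 / n)
  # single event among censored subjects: one step, curve reaches exp(-inc)
  rec1 <- surv_records(1:4, c(5, 1, 2, 3), c(1, 0, 0, 0))
  bh1 <- breslow_baseline(rep(0, 4), rec1)
  expect_length(bh1$event_times, 1)
  sc <- survival_curve(bh1, 0)
  expect_equal(sc$survival[nrow(sc)], exp(-bh1$cumulative_hazard))
  # random instances (incl. ties) vs the brute-force oracle
  for (seed in 1:50) {
    inst <- random_instance(8, seed, tie_grid = if (seed %% 2) NULL else 1:3)
    got <- breslow_baseline(inst$h, inst$records)
    want <- oracle_breslow(inst$h, inst$time, inst$event)
    expect_equal(got$event_times, want$event_times)
    expect_equal(got$cumulative_hazard, want$cumulative_hazard,
                 tolerance = 1e-12)
  }
})

test_that("survival curves exponentiate the baseline with the relative hazard", {
  inst <- random_instance(10, 3)
  bh <- breslow_baseline(inst$h, inst$records)
  sc0 <- survival_curve(bh, 0)
  expect_equal(sc0$survival, c(1, exp(-bh$cumulative_hazard)))
  sc <- survival_curve(bh, 0.7)
  expect_equal(sc$survival, c(1, exp(-bh$cumulative_hazard * exp(0.7))))
  # protective limit: very negative risk -> survival ~ 1 everywhere
  sc_low <- survival_curve(bh, -40)
  expect_true(all(sc_low$survival > 1 - 1e-6))
  # invariants
  expect_true(all(diff(sc$survival) <= 0))
  expect_true(all(sc$survival >= 0 & sc$survival <= 1))
})

test_that("breslow + survival_curve at h=0 equals the Nelson-Aalen exponential", {
  set.seed(11)
  time <- rexp(30, 1 / 50) + 1   # continuous: no ties
  event <- rbinom(30, 1, 0.7); event[1] <- 1
  rec <- surv_records(1:30, time, event)
  sc <- survival_curve(breslow_baseline(rep(0, 30), rec), 0)
  # direct Nelson-Aalen oracle
  ut <- sort(unique(time[event == 1]))
  na <- cumsum(vapply(ut, function(t) sum(time == t & event == 1) /
                        sum(time >= t), 1))
  expect_equal(sc$survival, c(1, exp(-na)), tolerance = 1e-12)
})

test_that("median survival time interpolates, extrapolates, and is antitone in risk", {
  # exponential curve with median 100 days
  tt <- seq(0, 400, by = 1)
  curve <- data.frame(time = tt, survival = exp(-(log(2) / 100) * tt))
  m <- median_survival_time(curve)
  expect_false(m$extrapolated)
  expect_equal(m$time, 100, tolerance = 0.5)
  # coarse two-point curve: linear interpolation between the bracketing
  # points (0, 1) and (50, 0.4) places the 0.5 crossing at 5/6 * 50
  step <- data.frame(time = c(0, 50), survival = c(1, 0.4))
  expect_equal(median_survival_time(step)$time, (1 - 0.5) / (1 - 0.4) * 50,
               tolerance = 1e-10)
  # exponential-tail extrapolation: closed form ln2 * t_last / (-ln S_last)
  flat <- data.frame(time = c(0, 100, 400), survival = c(1, 0.9, 0.8))
  m2 <- median_survival_time(flat, horizon = 1e5)
  expect_true(m2$extrapolated)
  expect_equal(m2$time, log(2) * 400 / (-log(0.8)), tolerance = 1e-10)
  # horizon cap
  m3 <- median_survival_time(flat, horizon = 800)
  expect_equal(m3$time, 800)
  expect_error(median_survival_time(data.frame(time = numeric(0),
                                               survival = numeric(0))))
  # antitone in risk for a shared baseline
  inst <- random_instance(40, 5)
  bh <- breslow_baseline(inst$h, inst$records)
  hs <- sort(rnorm(10, sd = 2))
  times <- predict_median_times(bh, hs, horizon = 1e5)$time
  expect_true(all(diff(times) <= 1e-9))
})

test_that("survival curves round-trip through delimited text", {
  inst <- random_instance(12, 9)
  sc <- survival_curve(breslow_baseline(inst$h, inst$records), 0.3)
  path <- tempfile(fileext = ".tsv")
  write_survival_curve(sc, path)
  back <- read_survival_curve(path)
  expect_equal(back$time, sc$time)
  expect_equal(back$survival, sc$survival, tolerance = 1e-12)
})
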