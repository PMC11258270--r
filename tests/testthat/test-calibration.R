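make_gtt_rows <- function(condition = "hyper", signal = "glucose",
                          times = c(0, 8), means = c(10, 20),
                          sems = c(0.4, 3), window = "d1", n = 3) {
  data.frame(condition = condition, signal = signal, time_h = times,
             mean = means, sem = sems, n = n, gtt_window = window,
             stringsAsFactors = FALSE)
}

test_that("SEM floor replaces unrealistically small values by the dataset max", {
  d <- make_gtt_rows(means = c(10, 20), sems = c(0.4, 3))
  # isolate the floor rule: nominal equals the measured t = 0 mean
  out <- preprocess_sem(d, nominal = c(glucose = 10, insulin = 0))
  expect_equal(out$sem, c(3, 3))  # 0.4 < 5% of 10, replaced by max SEM

  # all SEMs realistic and a zero t = 0 offset: identity
  d2 <- make_gtt_rows(means = c(10, 20), sems = c(0.6, 3))
  out2 <- preprocess_sem(d2, nominal = c(glucose = 10, insulin = 0))
  expect_equal(out2$sem, d2$sem)

  expect_error(preprocess_sem(make_gtt_rows(sems = c(0, 0))),
               "all SEM values are zero")
})

test_that("the measured exchange offset inflates every SEM of its window", {
  d <- make_gtt_rows(times = c(0, 8, 24), means = c(12, 9, 6),
                     sems = c(1, 1.5, 1))
  out <- preprocess_sem(d, nominal = c(glucose = 11, insulin = 0))
  expect_equal(out$sem, c(1, 1.5, 1) + 1)  # |12 - 11| added throughout

  # windows are independent and per-signal nominals are honoured
  d2 <- rbind(make_gtt_rows(times = c(0, 8), means = c(11, 9),
                            sems = c(1, 1), window = "d1"),
              make_gtt_rows(times = c(288, 296), means = c(13, 9),
                            sems = c(1, 1), window = "d13"))
  out2 <- preprocess_sem(d2, nominal = c(glucose = 11, insulin = 0))
  expect_equal(out2$sem, c(1, 1, 3, 3))
})

test_that("cost is the SEM-weighted residual sum and matches a naive oracle", {
  p <- default_parameters("H2")
  proto <- list(hyper = gtt_protocol(11, gtt_days = c(1, 7)))
  sim <- simulate_protocol(p, proto$hyper)
  d <- data.frame(condition = "hyper",
                  signal = rep(c("glucose", "insulin"),
                               each = nrow(sim$samples)),
                  time_h = rep(sim$samples$time, 2),
                  mean = c(sim$samples$glucose, sim$samples$insulin),
                  sem = 1, n = 3,
                  gtt_window = rep(sim$samples$window, 2),
                  stringsAsFactors = FALSE)
  # data generated noiselessly from the parameters: zero cost
  expect_equal(gtt_cost(p, d, proto), 0, tolerance = 1e-10)

  # every residual exactly one SEM: cost equals the number of points
  d1 <- d; d1$mean <- d1$mean + d1$sem
  expect_equal(gtt_cost(p, d1, proto), nrow(d1), tolerance = 1e-7)

  # reordering rows leaves the cost unchanged
  set.seed(1)
  d2 <- d1[sample(nrow(d1)), ]
  expect_equal(gtt_cost(p, d2, proto), gtt_cost(p, d1, proto))

  # scaling all SEMs by c scales the cost by 1/c^2
  d3 <- d1; d3$sem <- 2 * d3$sem
  expect_equal(gtt_cost(p, d3, proto), gtt_cost(p, d1, proto) / 4)

  # random perturbation: agrees with the spreadsheet-style re-summation
  set.seed(7)
  d4 <- d; d4$mean <- d4$mean * (1 + 0.2 * rnorm(nrow(d4))); d4$sem <- runif(nrow(d4), 0.5, 3)
  p4 <- default_parameters("H2", S_I0 = 0.07, sigma_max = 3e5)
  expect_equal(gtt_cost(p4, d4, proto), naive_cost(p4, d4, proto),
               tolerance = 1e-10)

  # a data time with no simulated sample is an error
  d5 <- d; d5$time_h[1] <- 3.7
  expect_error(gtt_cost(p, d5, proto), "no simulated sample")
})

test_that("chi-squared thresholds match the printed rejection gates", {
  expect_equal(round(chi2_threshold(25, 0.05), 2), 37.65)
  expect_equal(round(chi2_threshold(6, 0.05), 2), 12.59)
  expect_lt(chi2_threshold(1, 0.9999), 1e-3)
  expect_error(chi2_threshold(0), "positive integer")
  expect_error(chi2_threshold(2.5), "positive integer")
  expect_error(chi2_threshold(5, 1.2), "alpha")

  # strictly increasing in df, decreasing in alpha
  dfs <- 1:40
  expect_true(all(diff(vapply(dfs, chi2_threshold, numeric(1))) > 0))
  alphas <- seq(0.01, 0.5, by = 0.05)
  th <- vapply(alphas, function(a) chi2_threshold(10, a), numeric(1))
  expect_true(all(diff(th) < 0))

  # cross-check against an independent incomplete-gamma inversion
  for (df in c(1, 6, 25, 60)) {
    q <- stats::uniroot(function(x)
      pgamma(x, shape = df / 2, scale = 2) - 0.95,
      c(1e-8, 500), tol = 1e-10)$root
    expect_equal(chi2_threshold(df, 0.05), q, tolerance = 1e-6)
  }
})

test_that("the fitter is deterministic, respects bounds, and gates by cost", {
  st <- noiseless_study(default_parameters("H2"), gtt_days = c(1, 7))
  base <- default_parameters("H2", sigma_max = 2e5)
  free <- free_parameters("sigma_max", lower = 1e4, upper = 1e7)
  cfg <- quick_search(seed = 3, n_iter = 40, n_restarts = 1)

  e1 <- fit_ensemble(base, st$data, st$protocols, free, cfg)
  e2 <- fit_ensemble(base, st$data, st$protocols, free, cfg)
  expect_identical(e1$par, e2$par)          # same seed, same ensemble
  expect_identical(e1$cost, e2$cost)
  expect_true(all(e1$cost <= e1$threshold))
  expect_true(all(e1$par >= 1e4 & e1$par <= 1e7))
  expect_equal(e1$best, which.min(e1$cost))

  # degenerate gate: an infinite threshold accepts every evaluation
  e3 <- fit_ensemble(base, st$data, st$protocols, free,
                     quick_search(seed = 3, n_iter = 30, n_restarts = 1),
                     alpha = 1e-300)
  expect_equal(ensemble_size(e3), e3$n_eval)
})

test_that("noiseless single-parameter recovery hits the truth", {
  truth <- default_parameters("H2")
  st <- noiseless_study(truth, gtt_days = c(1, 7))
  base <- default_parameters("H2", sigma_max = 1.2e6)
  free <- free_parameters("sigma_max")
  ens <- fit_ensemble(base, st$data, st$protocols, free,
                      quick_search(seed = 2, n_iter = 60))
  expect_lt(abs(ens$best_par[["sigma_max"]] / truth$fast$sigma_max - 1),
            0.05)
})

test_that("envelopes bracket the central trajectory", {
  st <- noiseless_study(default_parameters("H2"), gtt_days = c(1, 7))
  base <- default_parameters("H2")
  free <- free_parameters("baseline")
  ens <- fit_ensemble(base, st$data, st$protocols, free,
                      quick_search(seed = 5, n_iter = 60))
  expect_gt(ensemble_size(ens), 2)
  env <- predict_envelope(ens, st$protocols$hyper)
  expect_true(all(env$lower <= env$central + 1e-12))
  expect_true(all(env$central <= env$upper + 1e-12))

  # a one-member ensemble collapses the envelope
  single <- ens
  single$par <- ens$par[ens$best, , drop = FALSE]
  single$cost <- ens$cost[ens$best]
  single$best <- 1L
  env1 <- predict_envelope(single, st$protocols$hyper)
  expect_equal(env1$lower, env1$central)
  expect_equal(env1$upper, env1$central)

  # when members coincide with the per-parameter extremes, the
  # extreme-member scheme equals brute force over the whole ensemble
  toy <- ens
  keep <- unique(c(ens$best,
                   apply(ens$par, 2, which.min),
                   apply(ens$par, 2, which.max)))
  toy$par <- ens$par[keep, , drop = FALSE]
  toy$cost <- ens$cost[keep]
  toy$best <- which.min(toy$cost)
  ex <- predict_envelope(toy, st$protocols$hyper, members = "extremes")
  all_ <- predict_envelope(toy, st$protocols$hyper, members = "all")
  expect_equal(ex$lower, all_$lower)
  expect_equal(ex$upper, all_$upper)

  empty <- ens; empty$par <- ens$par[0, , drop = FALSE]
  empty$flagged <- TRUE
  expect_error(predict_envelope(empty, st$protocols$hyper),
               "empty acceptable set")
})
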