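valid_from_sim <- function(params, protocol, window = "d1", sem = 0.5,
                           condition = "hyper") {
  s <- simulate_protocol(params, protocol)$samples
  s <- s[s$window == window, ]
  data.frame(condition = condition,
             signal = rep(c("glucose", "insulin"), each = nrow(s)),
             time_h = rep(s$time, 2), mean = c(s$glucose, s$insulin),
             sem = sem, n = 3, gtt_window = window,
             stringsAsFactors = FALSE)
}

test_that("hypothesis verdicts follow the ensemble's best validation cost", {
  base <- default_parameters("H2")
  proto <- list(hyper = gtt_protocol(11, gtt_days = c(1, 7)))
  ens <- make_ensemble(base, list(c(S_I0 = 0.1, sigma_max = 4e5),
                                  c(S_I0 = 0.08, sigma_max = 3e5)))
  # validation data generated noiselessly from a member: accepted at ~0
  v <- valid_from_sim(base, proto$hyper, "d7")
  out <- test_hypothesis(ens, v, proto)
  expect_equal(out$verdict, "accepted")
  expect_lt(out$min_cost, 1e-8)
  expect_equal(out$df, nrow(v))

  # data displaced by ten SEMs everywhere: cost >= 100 * N, rejected
  v10 <- v; v10$mean <- v10$mean + 10 * v10$sem
  out10 <- test_hypothesis(ens, v10, proto)
  expect_equal(out10$verdict, "rejected")
  expect_gte(out10$min_cost, 100 * nrow(v10) - 1e-6)

  # verdict is invariant to ensemble ordering
  ens_rev <- make_ensemble(base, list(c(S_I0 = 0.08, sigma_max = 3e5),
                                      c(S_I0 = 0.1, sigma_max = 4e5)),
                           cost = c(1, 0))
  out_rev <- test_hypothesis(ens_rev, v, proto)
  expect_equal(out_rev$verdict, out$verdict)
  expect_equal(out_rev$min_cost, out$min_cost)

  empty <- ens; empty$par <- ens$par[0, , drop = FALSE]
  expect_error(test_hypothesis(empty, v, proto), "empty")
})

test_that("dose design returns the smallest dose separating the envelopes", {
  base <- default_parameters("H2")
  ens_a <- make_ensemble(base, list(c(S_I0 = 0.1, sigma_max = 4e5)))
  ens_b <- make_ensemble(as_low_hct(default_parameters("H1", S_I0 = 0.012)),
                         list(c(S_I0 = 0.012, sigma_max = 4e5)))
  doses <- nM_to_mIU(c(1, 5, 25))
  pf <- function(dose) gtt_protocol(11, gtt_days = c(1, 13),
                                    spike_insulin = dose)
  # identical ensembles never discriminate at any required separation
  same <- design_discriminating_dose(ens_a, ens_a, doses, pf, sem_bar = 0)
  expect_true(is.na(same$dose))
  expect_equal(same$profile$glucose_gap, rep(0, 3), tolerance = 1e-9)

  # distinct ensembles with a zero SEM bar: smallest dose with any gap
  zero <- design_discriminating_dose(ens_a, ens_b, doses, pf, sem_bar = 0)
  expect_equal(zero$dose, doses[1])

  # raising the required separation never yields a smaller chosen dose
  gaps <- zero$profile$glucose_gap
  bars <- c(0, sort(gaps) * 0.99, max(gaps) * 1.01)
  chosen <- vapply(bars, function(bar) {
    res <- design_discriminating_dose(ens_a, ens_b, doses, pf,
                                      sem_bar = bar)
    if (is.na(res$dose)) Inf else res$dose
  }, numeric(1))
  expect_true(all(diff(chosen) >= 0))
  # an unreachable separation yields an explicit none-found result
  none <- design_discriminating_dose(ens_a, ens_b, doses, pf,
                                     sem_bar = max(gaps) + 1)
  expect_true(is.na(none$dose))
  expect_false(any(none$profile$discriminates))
})

test_that("hand-set constant separations obey the SEM-gap rule", {
  # gap 2.0 against a required 1.5 discriminates; gap 1.0 does not:
  # emulate with two flat-response parameter sets whose day-13 glucose
  # envelopes differ by a controlled amount
  base <- default_parameters("H2")
  ens_a <- make_ensemble(base, list(c(S_I0 = 0.1, sigma_max = 4e5)))
  ens_b <- make_ensemble(as_low_hct(default_parameters("H1", S_I0 = 0.012)),
                         list(c(S_I0 = 0.012, sigma_max = 4e5)))
  pf <- function(dose) gtt_protocol(11, gtt_days = c(1, 13),
                                    spike_insulin = dose)
  probe <- design_discriminating_dose(ens_a, ens_b, nM_to_mIU(25), pf,
                                      sem_bar = 0)
  gap <- probe$profile$glucose_gap
  expect_gt(gap, 0)
  below <- design_discriminating_dose(ens_a, ens_b, nM_to_mIU(25), pf,
                                      sem_bar = gap * 0.75)
  above <- design_discriminating_dose(ens_a, ens_b, nM_to_mIU(25), pf,
                                      sem_bar = gap * 1.25)
  expect_false(is.na(below$dose))
  expect_true(is.na(above$dose))
})

test_that("low-HCT prediction re-optimises only the baseline pair", {
  proto13 <- list(hyper = gtt_protocol(11, gtt_days = 1,
                                       duration_days = 3))
  # high-HCT optimum whose declines are already off reproduces itself
  opt <- c(S_I0 = 0.1, sigma_max = 4e5)
  ens_high <- make_ensemble(default_parameters("H2"), list(opt))
  truth_low <- as_low_hct(default_parameters("H1"))
  baseline <- valid_from_sim(truth_low, proto13$hyper, "d1", sem = 0.4)
  pred <- predict_low_hct(ens_high, baseline, proto13, proto13$hyper,
                          config = quick_search(seed = 4, n_iter = 60))
  expect_true(pred$reliable)
  est <- pred$ensemble$best_par
  expect_lt(abs(est[["S_I0"]] / opt[["S_I0"]] - 1), 0.05)
  expect_lt(abs(est[["sigma_max"]] / opt[["sigma_max"]] - 1), 0.05)
  env <- pred$envelope
  expect_true(all(env$lower <= env$central + 1e-9))
  expect_true(all(env$central <= env$upper + 1e-9))

  # a doubled secretion capacity in the generator is recovered
  truth2 <- update_parameters(truth_low, c(sigma_max = 8e5))
  baseline2 <- valid_from_sim(truth2, proto13$hyper, "d1", sem = 0.4)
  pred2 <- predict_low_hct(ens_high, baseline2, proto13, proto13$hyper,
                           config = quick_search(seed = 5, n_iter = 60))
  expect_lt(abs(pred2$ensemble$best_par[["sigma_max"]] / 8e5 - 1), 0.10)
})

test_that("without declines the late dynamics repeat the baseline", {
  # time-homogeneity: with all decline magnitudes zero, each GTT window
  # under identical dosing reproduces the day-1 response (up to the tiny
  # slow beta-cell drift)
  p <- as_low_hct(default_parameters("H1", I_max_Si = 0, k_v = 0))
  sim <- simulate_protocol(p, gtt_protocol(11, gtt_days = c(1, 13)))
  s <- sim$samples
  g1 <- s$glucose[s$window == "d1"]
  g13 <- s$glucose[s$window == "d13"]
  expect_equal(g13, g1, tolerance = 1e-6)
  expect_equal(s$insulin[s$window == "d13"],
               s$insulin[s$window == "d1"], tolerance = 1e-6)
})
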