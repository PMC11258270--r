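test_that("protocol factory reproduces the 15-day chip design", {
  p <- gtt_protocol(maintenance_glucose = 11, gtt_days = c(1, 7, 13),
                    spike_insulin = nM_to_mIU(24))
  ev <- p$events
  expect_equal(ev$time, seq(0, 288, by = 48))
  expect_true(all(ev$kind == "MEDIUM_EXCHANGE"))
  expect_equal(ev$glucose_conc, rep(11, 7))
  expect_equal(ev$applies_offsets[ev$time == 0], "d1")
  expect_equal(ev$applies_offsets[ev$time == 288], "d13")
  expect_equal(ev$insulin_conc[ev$time == 288], 4000)
  expect_equal(sum(ev$insulin_conc > 0), 1)
  s <- p$sampling
  expect_equal(s$time[s$window == "d7"], 144 + c(0, 8, 24, 48))
  expect_equal(s$take[s$window == "d13"], c("post", "pre", "pre", "pre"))
  expect_equal(p$duration, 336)
  # normoglycemic arm keeps the 11 mM load only inside GTT windows
  pn <- gtt_protocol(maintenance_glucose = 5.5, gtt_days = c(1, 13))
  expect_equal(sort(unique(pn$events$glucose_conc)), c(5.5, 11))
  expect_error(mps_protocol(ev[c(2, 1), ], s, 336), "time-ordered")
})

test_that("events reset or add amounts and never touch slow states", {
  p <- default_parameters("H1", dG_d13 = 0.5, dI_d13 = 3)
  s0 <- model_state(NG_m_liver = 1e-3, NI_m_liver = 1e-2, G_int = 50,
                    G_slow_pancreas = 9, V_beta_islets = 2e-9,
                    t_state = 288)
  ex <- protocol_event(288, "MEDIUM_EXCHANGE", glucose_conc = 11)
  s1 <- apply_event(s0, ex, p)
  expect_equal(s1[["NG_m_liver"]], 11 * p$geometry$V_m_liver)
  expect_equal(s1[["NI_m_pancreas"]], 0)
  expect_equal(s1[c("G_int", "G_slow_pancreas", "V_beta_islets", "t_state")],
               s0[c("G_int", "G_slow_pancreas", "V_beta_islets", "t_state")])

  ex13 <- protocol_event(288, "MEDIUM_EXCHANGE", glucose_conc = 11,
                         applies_offsets = "d13")
  s2 <- apply_event(s0, ex13, p)
  expect_equal(s2[["NG_m_liver"]], 11.5 * p$geometry$V_m_liver)
  expect_equal(s2[["NI_m_liver"]], 3 * p$geometry$V_m_liver)

  # idempotence: two identical consecutive exchanges equal one
  expect_equal(apply_event(s1, ex, p), s1)

  sp0 <- protocol_event(288, "INSULIN_SPIKE", insulin_conc = 0)
  expect_equal(apply_event(s0, sp0, p), s0)   # zero spike is the identity
  sp <- protocol_event(288, "INSULIN_SPIKE", insulin_conc = 100)
  s3 <- apply_event(s0, sp, p)
  expect_equal(s3[["NI_m_liver"]] - s0[["NI_m_liver"]],
               100 * p$geometry$V_m_liver)
  expect_equal(s3[["NG_m_liver"]], s0[["NG_m_liver"]])
  s4 <- apply_event(s0, sp, p, compartments = "liver")
  expect_equal(s4[["NI_m_pancreas"]], s0[["NI_m_pancreas"]])
})

test_that("inert chip conserves mass and mixes to the volume-weighted mean", {
  p <- inert_parameters()
  proto <- gtt_protocol(maintenance_glucose = 11, gtt_days = c(1, 7, 13))
  sim <- simulate_protocol(p, proto)
  # pooled glucose stays at the dosed 11 mM at every sampling time
  expect_equal(sim$samples$glucose, rep(11, nrow(sim$samples)),
               tolerance = 1e-8)
  tr <- sim$trajectory
  totG <- tr$NG_m_liver + tr$NG_m_pancreas
  totI <- tr$NI_m_liver + tr$NI_m_pancreas
  expect_lt(max(abs(totG / totG[1] - 1)), 1e-8)

  # asymmetric start: both compartments relax exponentially to the common
  # volume-weighted mean (equal volumes here, so (14 + 2) / 2 = 8)
  s0 <- model_state(NG_m_liver = 14 * p$geometry$V_m_liver,
                    NG_m_pancreas = 2 * p$geometry$V_m_pancreas)
  proto2 <- mps_protocol(events = protocol_event(1e9, "INSULIN_SPIKE")[0, ],
                         sampling = data.frame(time = 96, window = NA,
                                               take = "pre"),
                         duration = 96, initial_glucose = 8)
  sim2 <- simulate_protocol(p, proto2, init = s0)
  tr2 <- sim2$trajectory
  Gl <- tr2$NG_m_liver / p$geometry$V_m_liver
  Gp <- tr2$NG_m_pancreas / p$geometry$V_m_pancreas
  expect_equal(tail(Gl, 1), 8, tolerance = 1e-6)
  expect_equal(tail(Gp, 1), 8, tolerance = 1e-6)
  expect_true(all(diff(Gl) <= 1e-6))   # monotone exponential approach
  expect_true(all(diff(Gp) >= -1e-6))
})

test_that("trajectories are solver-converged and grid-invariant", {
  p <- default_parameters("H2")
  proto <- gtt_protocol(maintenance_glucose = 11, gtt_days = c(1, 7, 13))
  base <- simulate_protocol(p, proto)
  tight <- simulate_protocol(p, proto,
                             solver_config(rtol = 5e-9, atol = 5e-11))
  expect_equal(base$samples$glucose, tight$samples$glucose,
               tolerance = 1e-6)
  expect_equal(base$samples$insulin, tight$samples$insulin,
               tolerance = 1e-6)
  # refining the recorded grid leaves shared sampling times unchanged
  fine <- simulate_protocol(p, proto, solver_config(dt_record = 1))
  expect_equal(fine$samples$glucose, base$samples$glucose,
               tolerance = 1e-9)
  # determinism
  again <- simulate_protocol(p, proto)
  expect_identical(again$samples, base$samples)
})

test_that("compiled and R reference right-hand sides agree", {
  p <- default_parameters("H2", dG_d1 = 0.3, dI_d1 = 1)
  proto <- gtt_protocol(maintenance_glucose = 11, gtt_days = c(1, 7))
  a <- simulate_protocol(p, proto, solver_config(engine = "compiled"))
  b <- simulate_protocol(p, proto, solver_config(engine = "R"))
  expect_equal(a$samples$glucose, b$samples$glucose, tolerance = 1e-7)
  expect_equal(a$samples$insulin, b$samples$insulin, tolerance = 1e-7)
})

test_that("secreted insulin matches an independent quadrature when Q = 0", {
  # flow off, fixed pancreas glucose; NI_pancreas grows by the integral of
  # V_beta(t) * sigma(t) * Hill(G): cross-check with nested quadrature
  p <- default_parameters("H1", Q = 1e-12, S_I0 = 0,
                          k_elimination_I_spheroids = 0, E_G0 = 0)
  Gfix <- 8
  proto <- mps_protocol(
    events = protocol_event(1e9, "INSULIN_SPIKE")[0, ],
    sampling = data.frame(time = 48, window = NA, take = "pre"),
    duration = 48, initial_glucose = Gfix)
  sim <- simulate_protocol(p, proto)
  # independent reconstruction
  s <- p$slow
  Gslow <- function(t) Gfix + (5.5 - Gfix) * exp(-t / s$tau_slow)
  growth <- function(t) s$k_v * (-s$d_0 + s$r1 * Gslow(t) -
                                   s$r2 * Gslow(t)^2)
  Vb <- function(t) vapply(t, function(ti)
    s$V_beta_0 * exp(stats::integrate(growth, 0, ti,
                                      rel.tol = 1e-10)$value), numeric(1))
  hill <- Gfix^2 / (p$fast$EC50_I^2 + Gfix^2)
  secr <- function(t) Vb(t) * secretion_capacity(t, p) * hill
  NIp_expect <- stats::integrate(secr, 0, 48, rel.tol = 1e-10)$value
  # pooled observable: insulin only in the pancreas compartment
  pooled_expect <- 0.5 * NIp_expect / p$geometry$V_m_pancreas
  expect_equal(sim$samples$insulin, pooled_expect, tolerance = 1e-6)
})

test_that("samples at event times are drawn post-event by default", {
  p <- default_parameters("H1")
  ev <- rbind(protocol_event(0, "MEDIUM_EXCHANGE", glucose_conc = 11,
                             applies_offsets = "d1"),
              protocol_event(48, "MEDIUM_EXCHANGE", glucose_conc = 5.5))
  proto <- mps_protocol(
    events = ev,
    sampling = data.frame(time = c(48, 48), window = c("w", "w"),
                          take = c("pre", "post")),
    duration = 96)
  sim <- simulate_protocol(p, proto)
  post <- sim$samples$glucose[sim$samples$take == "post"]
  pre <- sim$samples$glucose[sim$samples$take == "pre"]
  expect_equal(post, 5.5)          # freshly exchanged medium
  expect_lt(pre, 11)               # end of the preceding segment,
  expect_gt(abs(pre - post), 0.1)  # distinct from the fresh medium
})
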