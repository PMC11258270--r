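# End-to-end in-silico study replicas. Each function generates a
# synthetic chip study under known ground truth, runs the corresponding
# analysis workflow, and scores the outcome against the sealed truth.
# They are the package's self-validation harnesses: deterministic given
# the seed, with study conditions fixed to the shipped defaults.

#' Replicate the hypothesis-discrimination study in silico
#'
#' Generates a two-arm (hyperglycemic / normoglycemic) 15-day GTT study
#' under the two-factor hypothesis H2 with a strong additional
#' diabetogenic factor and an insulin dose spiked at the day-13 GTT,
#' calibrates H1 and H2 on the day 1-3 and 7-9 windows (donor parameters
#' `S_I0` and `sigma_max` free), and tests both hypotheses on the held-out
#' day 13-15 spiked GTT. Calibration and validation windows are
#' preprocessed separately (they are distinct experiments) with
#' per-signal SEM floors.
#'
#' @param seed RNG seed for the generated study and the search.
#' @param noise_cv replicate measurement noise (default 0.05, the assay
#'   noise floor the SEM preprocessing assumes).
#' @param n_circuits replicate circuits per arm.
#' @param spike_insulin validation insulin dose (mIU/L; default 24 nM).
#' @param search a [search_config()] (its seed is overridden by `seed`).
#' @param solver a [solver_config()].
#' @return A list: `h1`, `h2` ([test_hypothesis()] verdicts), `h1_calib`,
#'   `h2_calib` (best calibration costs), `calib_threshold`.
#' @export
discrimination_study <- function(seed, noise_cv = 0.05, n_circuits = 3,
                                 spike_insulin = nM_to_mIU(24),
                                 search = search_config(n_restarts = 2,
                                                        n_iter = 120),
                                 solver = solver_config()) {
  truth <- default_parameters("H2", dG_d1 = 0.4, dI_d1 = 2)
  des <- study_design(conditions = c(hyper = 11, normo = 5.5),
                      n_circuits = n_circuits, noise_cv = noise_cv,
                      spike_insulin = spike_insulin, seed = seed)
  st <- generate_gtt_study(truth, des, solver)
  nom <- data.frame(gtt_window = rep(c("d1", "d7", "d13"), each = 2),
                    signal = rep(c("glucose", "insulin"), 3),
                    nominal = c(11, 0, 11, 0, 11, spike_insulin),
                    stringsAsFactors = FALSE)
  calib <- preprocess_sem(st$data[st$data$gtt_window != "d13", ], nom,
                          per_signal = TRUE)
  valid <- preprocess_sem(st$data[st$data$gtt_window == "d13", ], nom,
                          per_signal = TRUE)
  search$seed <- seed
  free <- free_parameters("baseline")
  e2 <- fit_ensemble(default_parameters("H2"), calib, st$protocols,
                     free, search, solver = solver)
  e1 <- fit_ensemble(default_parameters("H1"), calib, st$protocols,
                     free, search, solver = solver)
  list(h1 = test_hypothesis(e1, valid, st$protocols, solver = solver),
       h2 = test_hypothesis(e2, valid, st$protocols, solver = solver),
       h1_calib = e1$best_cost, h2_calib = e2$best_cost,
       calib_threshold = e1$threshold)
}

#' Replicate the donor-parameter recovery study in silico
#'
#' Generates a single-arm hyperglycemic GTT study under H2 with
#' perturbed donor parameters, fits `S_I0` and `sigma_max` from a
#' deliberately wrong starting point, and reports the relative recovery
#' errors against the sealed truth.
#'
#' @param seed RNG seed.
#' @param noise_cv replicate measurement noise (default 0.10); `0` gives
#'   the noiseless benchmark, with SEM weights set to
#'   `max(5% of mean, 0.1)`.
#' @param n_circuits replicate circuits.
#' @param search a [search_config()].
#' @param solver a [solver_config()].
#' @return A list: `err` (named relative errors for `S_I0`,
#'   `sigma_max`), `estimate`, `truth`, `best_cost`.
#' @export
recovery_study <- function(seed, noise_cv = 0.10, n_circuits = 4,
                           search = search_config(n_restarts = 2,
                                                  n_iter = 120),
                           solver = solver_config()) {
  donor <- c(S_I0 = 0.8, sigma_max = 1.3)   # donor-shifted truth
  des <- study_design(conditions = c(hyper = 11),
                      n_circuits = n_circuits, noise_cv = noise_cv,
                      gtt_days = c(1, 7), donor_effect = donor,
                      seed = seed)
  st <- generate_gtt_study(default_parameters("H2"), des, solver)
  d <- if (noise_cv > 0) preprocess_sem(st$data, per_signal = TRUE) else {
    st$data$sem <- pmax(0.05 * abs(st$data$mean), 0.1)
    st$data
  }
  search$seed <- seed
  base <- default_parameters("H2", S_I0 = 0.03, sigma_max = 1.5e6)
  ens <- fit_ensemble(base, d, st$protocols, free_parameters("baseline"),
                      search, solver = solver)
  truth <- unseal(st$truth)$params
  tv <- c(S_I0 = truth$fast$S_I0, sigma_max = truth$fast$sigma_max)
  est <- ens$best_par[names(tv)]
  list(err = abs(est / tv - 1), estimate = est, truth = tv,
       best_cost = ens$best_cost)
}

#' Replicate the low-hydrocortisone prediction study in silico
#'
#' Calibrates H2 on a high-HCT study (declines active), then predicts a
#' low-HCT study generated with both declines disabled: the baseline
#' day 1-3 low-HCT GTT re-calibrates `S_I0` and `sigma_max`, and the
#' resulting envelope is scored for containment of the noiseless day
#' 13-15 glucose truth via the area under the GTT curve.
#'
#' @param seed RNG seed.
#' @param noise_cv replicate measurement noise (default 0.05).
#' @param search a [search_config()].
#' @param solver a [solver_config()].
#' @return A list: `auc_contained` (day-13 glucose AUC inside the
#'   envelope AUC band), `truth_auc`, `auc_band`, `reliable`,
#'   `baseline_cost`.
#' @export
low_hct_study <- function(seed, noise_cv = 0.05,
                          search = search_config(n_restarts = 2,
                                                 n_iter = 120),
                          solver = solver_config()) {
  # high-HCT arm: declines on, both glucose arms, no spike
  truth_high <- default_parameters("H2")
  des_high <- study_design(conditions = c(hyper = 11, normo = 5.5),
                           n_circuits = 3, noise_cv = noise_cv,
                           gtt_days = c(1, 13), seed = seed)
  st_high <- generate_gtt_study(truth_high, des_high, solver)
  d_high <- preprocess_sem(st_high$data, per_signal = TRUE)
  search$seed <- seed
  ens_high <- fit_ensemble(default_parameters("H2"), d_high,
                           st_high$protocols, free_parameters("baseline"),
                           search, solver = solver)

  # low-HCT arm: declines off, donor-shifted baseline
  truth_low <- as_low_hct(default_parameters("H1", S_I0 = 0.08,
                                             sigma_max = 4.5e5))
  des_low <- study_design(conditions = c(hyper = 11), n_circuits = 6,
                          noise_cv = noise_cv, gtt_days = c(1, 13),
                          seed = seed + 1000L)
  st_low <- generate_gtt_study(truth_low, des_low, solver)
  d_low <- preprocess_sem(st_low$data, per_signal = TRUE)
  baseline <- d_low[d_low$gtt_window == "d1", ]
  search2 <- search; search2$seed <- seed + 1L
  pred <- predict_low_hct(ens_high, baseline, st_low$protocols,
                          st_low$protocols$hyper, config = search2,
                          solver = solver)

  env <- pred$envelope
  env13 <- env[env$window == "d13" & env$signal == "glucose", ]
  tru <- unseal(st_low$truth)$curves$hyper
  tru13 <- tru[tru$window == "d13", ]
  lo <- auc_trapezoid(env13$time, env13$lower)
  hi <- auc_trapezoid(env13$time, env13$upper)
  truth_auc <- auc_trapezoid(tru13$time, tru13$glucose)
  list(auc_contained = truth_auc >= lo && truth_auc <= hi,
       truth_auc = truth_auc, auc_band = c(lower = lo, upper = hi),
       reliable = pred$reliable, baseline_cost = pred$baseline_cost)
}
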