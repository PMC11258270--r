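# Shared fixtures for the test suite: inert parameter settings (all
# exchange/uptake/secretion pathways switched off), small protocols, and
# reduced search budgets that keep the suite fast while exercising the
# full code paths.

inert_parameters <- function(hypothesis = "H1") {
  default_parameters(hypothesis, E_G0 = 0, S_I0 = 0, sigma_max = 0,
                     k_elimination_I_spheroids = 0, EGP = 0)
}

quick_search <- function(seed = 1, n_iter = 80, n_restarts = 2)
  search_config(n_restarts = n_restarts, n_iter = n_iter, seed = seed)

# one-condition hyperglycemic study with nominal SEM weights attached
noiseless_study <- function(true_params, seed = 1, gtt_days = c(1, 7)) {
  des <- study_design(conditions = c(hyper = 11), n_circuits = 4,
                      noise_cv = 0, gtt_days = gtt_days, seed = seed)
  st <- generate_gtt_study(true_params, des)
  st$data$sem <- pmax(0.05 * abs(st$data$mean), 0.1)
  st
}

spiked_nominals <- function(dose)
  data.frame(gtt_window = rep(c("d1", "d7", "d13"), each = 2),
             signal = rep(c("glucose", "insulin"), 3),
             nominal = c(11, 0, 11, 0, 11, dose))

# hand-built ensemble around explicit parameter rows (for workflow tests)
make_ensemble <- function(base, par_rows, free = free_parameters("baseline"),
                          cost = NULL, threshold = 100, df = 10) {
  par <- do.call(rbind, par_rows)
  colnames(par) <- free$name
  cost <- cost %||% seq(0, by = 1, length.out = nrow(par))
  structure(list(par = par, cost = cost, best = which.min(cost),
                 threshold = threshold, df = df, alpha = 0.05,
                 free = free, base = base, seed = 1L,
                 n_eval = nrow(par), flagged = FALSE,
                 best_par = par[which.min(cost), ],
                 best_cost = min(cost)),
            class = "mps_ensemble")
}
`%||%` <- function(a, b) if (is.null(a)) b else a
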