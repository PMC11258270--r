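# Independent oracles used to cross-check the implementation. Each is a
# deliberately literal, loop-style transcription of the governing
# equations, kept free of any package internals beyond plain parameter
# access.

# Literal transcription of the printed balance equations, one line per
# equation term, reading symbols straight from the parameter blocks.
literal_rhs <- function(state, params, G_d = 0) {
  geo <- params$geometry
  Vml <- geo$V_m_liver; Vmp <- geo$V_m_pancreas
  Vhep <- geo$V_HepaRG_spheroids; Q <- geo$Q
  fa <- params$fast
  NGl <- state[["NG_m_liver"]]; NGp <- state[["NG_m_pancreas"]]
  NIl <- state[["NI_m_liver"]]; NIp <- state[["NI_m_pancreas"]]
  Gint <- state[["G_int"]]; Gslow <- state[["G_slow_pancreas"]]
  Vb <- state[["V_beta_islets"]]; tt <- state[["t_state"]]

  # S_I(t): base hyperglycemia factor, times the additional factor for H2
  S_I <- fa$S_I0 * (1 - (fa$I_max_Si * Gint) / (fa$EC50_Si + Gint))
  if (params$hypothesis == "H2") {
    S_I <- S_I * (1 - (params$h2$I_max_additional * tt^2) /
                    (params$h2$EC50_additional^2 + tt^2))
  }
  # sigma(t): declining, except constant under the low-HCT variant
  sigma <- if (params$hypothesis == "LOW_HCT") fa$sigma_max else
    fa$sigma_max * (1 - tt^2 / (fa$alpha + tt^2))

  dNGl <- G_d + Vhep * fa$EGP -
    Vhep * (fa$E_G0 + S_I * (NIl / Vml)) * (NGl / Vml) +
    Q * (NGp / Vmp) - Q * (NGl / Vml)
  dNGp <- G_d + Q * (NGl / Vml) - Q * (NGp / Vmp)
  dNIl <- Q * (NIp / Vmp) - Q * (NIl / Vml) -
    Vhep * fa$k_elimination_I_spheroids * (NIl / Vml)
  Gp <- NGp / Vmp
  dNIp <- Vb * sigma * Gp^2 / (fa$EC50_I^2 + Gp^2) +
    Q * (NIl / Vml) - Q * (NIp / Vmp)
  excess <- NGl / Vml - fa$G_normo
  dGint <- if (excess >= 0) excess else 0
  dGslow <- (Gp - Gslow) / params$slow$tau_slow
  dVb <- params$slow$k_v *
    (-params$slow$d_0 + params$slow$r1 * Gslow -
       params$slow$r2 * Gslow^2) * Vb
  c(NG_m_liver = dNGl, NG_m_pancreas = dNGp, NI_m_liver = dNIl,
    NI_m_pancreas = dNIp, G_int = dGint, G_slow_pancreas = dGslow,
    V_beta_islets = dVb, t_state = 1)
}

# From-scratch two-way ANOVA decomposition (grand mean, row/column means,
# residuals) followed by the ICC(2,1) formula; explicit loops, no aov().
icc_sums_of_squares <- function(m, mode = "standard") {
  nr <- nrow(m); nt <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)   # judges (circuits)
  col_means <- colMeans(m)   # targets (timepoints)
  ss_target <- 0; ss_judge <- 0; ss_resid <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nt)) {
      ss_resid <- ss_resid +
        (m[i, j] - row_means[i] - col_means[j] + grand)^2
    }
  }
  for (j in seq_len(nt)) ss_target <- ss_target + nr * (col_means[j] - grand)^2
  for (i in seq_len(nr)) ss_judge <- ss_judge + nt * (row_means[i] - grand)^2
  MS_B <- ss_target / (nt - 1)
  MS_J <- ss_judge / (nr - 1)
  MS_E <- ss_resid / ((nr - 1) * (nt - 1))
  n_c <- if (mode == "standard") nt else nr * nt
  (MS_B - MS_E) / (MS_B + (nr - 1) * MS_E + nr * (MS_J - MS_E) / n_c)
}

# Naive spreadsheet-style re-summation of the weighted least-squares
# cost: one explicit loop over rows, simulations looked up per condition.
naive_cost <- function(params, data, protocols, solver = solver_config()) {
  sims <- lapply(unique(data$condition), function(cond)
    simulate_protocol(params, protocols[[cond]], solver))
  names(sims) <- unique(data$condition)
  total <- 0
  for (r in seq_len(nrow(data))) {
    s <- sims[[data$condition[r]]]$samples
    hit <- which(s$window == data$gtt_window[r] &
                   abs(s$time - data$time_h[r]) < 1e-9)
    pred <- if (data$signal[r] == "glucose") s$glucose[hit] else s$insulin[hit]
    total <- total + (data$mean[r] - pred)^2 / data$sem[r]^2
  }
  total
}

# random valid state / parameter draws for property-style loops
random_state <- function() {
  model_state(NG_m_liver = runif(1, 0, 5e-3),
              NG_m_pancreas = runif(1, 0, 5e-3),
              NI_m_liver = runif(1, 0, 0.05),
              NI_m_pancreas = runif(1, 0, 0.05),
              G_int = runif(1, 0, 800),
              G_slow_pancreas = runif(1, 0, 15),
              V_beta_islets = runif(1, 1e-10, 5e-8),
              t_state = runif(1, 0, 400))
}

random_params <- function(hypothesis = sample(c("H1", "H2", "LOW_HCT"), 1)) {
  default_parameters(
    hypothesis,
    E_G0 = runif(1, 0.05, 2), S_I0 = runif(1, 0.005, 0.5),
    I_max_Si = runif(1, 0, 1), EC50_Si = runif(1, 10, 500),
    sigma_max = runif(1, 1e4, 1e6), alpha = runif(1, 1e3, 1e5),
    EC50_I = runif(1, 2, 20),
    k_elimination_I_spheroids = runif(1, 0.5, 20))
}
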