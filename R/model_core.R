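# Core model equations: closed-form subexpressions, the R reference
# right-hand side, pooled observables and initial conditions. The compiled
# counterpart of ode_rhs() lives in src/mps_model.c (same parameter order).

.STATE_NAMES <- c("NG_m_liver", "NG_m_pancreas", "NI_m_liver",
                  "NI_m_pancreas", "G_int", "G_slow_pancreas",
                  "V_beta_islets", "t_state")

#' Construct a model state vector
#'
#' The eight dynamical states of the coupled fast/slow system: glucose
#' amounts (mmol) and insulin amounts (mIU) in the medium of each
#' compartment, the integral of excess glucose `G_int` (mmol h/L), the
#' long-term average glucose `G_slow_pancreas` (mmol/L), the beta-cell
#' volume `V_beta_islets` (L), and the elapsed co-culture time `t_state`
#' (h) carried as a state so the time-dependent declines survive
#' event-driven integration restarts.
#'
#' @param NG_m_liver,NG_m_pancreas glucose amounts (mmol).
#' @param NI_m_liver,NI_m_pancreas insulin amounts (mIU).
#' @param G_int integral of excess glucose (mmol h/L).
#' @param G_slow_pancreas long-term average glucose (mmol/L).
#' @param V_beta_islets beta-cell volume (L).
#' @param t_state elapsed co-culture time (h).
#' @return Named numeric vector of length 8.
#' @export
model_state <- function(NG_m_liver = 0, NG_m_pancreas = 0, NI_m_liver = 0,
                        NI_m_pancreas = 0, G_int = 0,
                        G_slow_pancreas = 5.5, V_beta_islets = 8.8e-9,
                        t_state = 0) {
  s <- c(NG_m_liver = NG_m_liver, NG_m_pancreas = NG_m_pancreas,
         NI_m_liver = NI_m_liver, NI_m_pancreas = NI_m_pancreas,
         G_int = G_int, G_slow_pancreas = G_slow_pancreas,
         V_beta_islets = V_beta_islets, t_state = t_state)
  if (any(!is.finite(s))) stop("model state must be finite")
  if (any(s[c(1:4, 7)] < 0))
    stop("amounts and beta-cell volume must be nonnegative")
  s
}

#' Insulin sensitivity of the liver spheroids
#'
#' \eqn{S_I} declines from its initial value `S_I0` with the accumulated
#' integral of excess glucose (all hypotheses):
#' \deqn{S_I = S_{I0} (1 - I_{max,Si} G_{int} / (EC50_{Si} + G_{int}))}
#' Under H2 it is additionally multiplied by the time-dependent
#' diabetogenic factor \eqn{1 - I_{max,add} t^2 / (EC50_{add}^2 + t^2)}.
#' The LOW_HCT variant keeps the hyperglycemia term but omits the
#' additional factor.
#'
#' @param t elapsed co-culture time (h), nonnegative.
#' @param G_int integral of excess glucose (mmol h/L), nonnegative.
#' @param params an [mps_parameters()] object.
#' @return Insulin sensitivity (L/mIU/h). Vectorized over `t` / `G_int`.
#' @export
insulin_sensitivity <- function(t, G_int, params) {
  if (any(t < 0) || any(G_int < 0))
    stop("t and G_int must be nonnegative")
  f <- params$fast
  si <- f$S_I0 * (1 - f$I_max_Si * G_int / (f$EC50_Si + G_int))
  if (params$hypothesis == "H2") {
    h2 <- params$h2
    si <- si * (1 - h2$I_max_additional * t^2 /
                  (h2$EC50_additional^2 + t^2))
  }
  si
}

#' Insulin secretion capacity of the beta cells
#'
#' Under H1/H2 the capacity declines sigmoidally in time,
#' \eqn{\sigma(t) = \sigma_{max} (1 - t^2/(\alpha + t^2))}, halving at
#' \eqn{t = \sqrt{\alpha}}. Under LOW_HCT the decline is omitted and
#' \eqn{\sigma(t) = \sigma_{max}} throughout.
#'
#' @inheritParams insulin_sensitivity
#' @return Secretion capacity (mIU/L/h per unit beta-cell volume).
#' @export
secretion_capacity <- function(t, params) {
  if (any(t < 0)) stop("t must be nonnegative")
  f <- params$fast
  if (params$hypothesis == "LOW_HCT") rep(f$sigma_max, length(t))
  else f$sigma_max * (1 - t^2 / (f$alpha + t^2))
}

#' Right-hand side of the coupled fast/slow ODE system
#'
#' Time-derivatives of the eight model states: glucose balance in each
#' compartment (dosing, endogenous production, insulin-dependent and
#' -independent hepatic uptake, flow exchange), insulin balance (Hill-type
#' beta-cell secretion, flow exchange, hepatic elimination), the excess
#' glucose integral, the slow glucose average, Topp-type beta-cell volume
#' dynamics, and the explicit time state.
#'
#' This is the documented R reference implementation; the solver used by
#' [simulate_protocol()] defaults to the identical compiled version.
#'
#' @param state named state vector, see [model_state()].
#' @param params an [mps_parameters()] object.
#' @param G_d continuous glucose dosing rate (mmol/h) applied to each
#'   compartment; 0 in all shipped protocols (exchanges are discrete
#'   events).
#' @return Named numeric vector of derivatives, same order as `state`.
#' @export
ode_rhs <- function(state, params, G_d = 0) {
  if (any(!is.finite(state))) stop("model state must be finite")
  if (G_d < 0) stop("G_d must be nonnegative")
  g <- params$geometry; f <- params$fast; s <- params$slow
  G_liver <- state[["NG_m_liver"]] / g$V_m_liver
  G_pancreas <- state[["NG_m_pancreas"]] / g$V_m_pancreas
  I_liver <- state[["NI_m_liver"]] / g$V_m_liver
  I_pancreas <- state[["NI_m_pancreas"]] / g$V_m_pancreas
  t <- state[["t_state"]]

  S_I <- insulin_sensitivity(t, state[["G_int"]], params)
  sigma <- secretion_capacity(t, params)

  dNG_liver <- G_d + g$V_HepaRG_spheroids * f$EGP -
    g$V_HepaRG_spheroids * (f$E_G0 + S_I * I_liver) * G_liver +
    g$Q * (G_pancreas - G_liver)
  dNG_pancreas <- G_d + g$Q * (G_liver - G_pancreas)
  dNI_liver <- g$Q * (I_pancreas - I_liver) -
    g$V_HepaRG_spheroids * f$k_elimination_I_spheroids * I_liver
  secretion <- state[["V_beta_islets"]] * sigma *
    G_pancreas^2 / (f$EC50_I^2 + G_pancreas^2)
  dNI_pancreas <- secretion + g$Q * (I_liver - I_pancreas)
  dG_int <- max(G_liver - f$G_normo, 0)
  dG_slow <- (G_pancreas - state[["G_slow_pancreas"]]) / s$tau_slow
  dV_beta <- s$k_v * (-s$d_0 + s$r1 * state[["G_slow_pancreas"]] -
                        s$r2 * state[["G_slow_pancreas"]]^2) *
    state[["V_beta_islets"]]

  setNames(c(dNG_liver, dNG_pancreas, dNI_liver, dNI_pancreas,
             dG_int, dG_slow, dV_beta, 1), .STATE_NAMES)
}

#' Pooled glucose and insulin observables
#'
#' GTT samples are drawn from both compartments and pooled; the simulated
#' observable is the sample-volume-weighted mean of the compartment
#' concentrations,
#' \deqn{(C_{liver} V_{s,liver} + C_{pancreas} V_{s,pancreas}) /
#'       (V_{s,liver} + V_{s,pancreas}),}
#' which reduces to the arithmetic mean for the default equal 15 ul draws.
#'
#' @param state named state vector (or a matrix with state columns).
#' @param geometry an [mps_geometry()] object.
#' @return Named numeric vector `c(G = , I = )` (mmol/L, mIU/L), or a
#'   two-column matrix for matrix input.
#' @export
pooled_observables <- function(state, geometry) {
  vs <- geometry$V_sample_liver + geometry$V_sample_pancreas
  if (vs <= 0) stop("total sample volume must be positive")
  wl <- geometry$V_sample_liver / vs
  wp <- geometry$V_sample_pancreas / vs
  if (is.matrix(state)) {
    cbind(G = wl * state[, "NG_m_liver"] / geometry$V_m_liver +
            wp * state[, "NG_m_pancreas"] / geometry$V_m_pancreas,
          I = wl * state[, "NI_m_liver"] / geometry$V_m_liver +
            wp * state[, "NI_m_pancreas"] / geometry$V_m_pancreas)
  } else {
    c(G = wl * state[["NG_m_liver"]] / geometry$V_m_liver +
        wp * state[["NG_m_pancreas"]] / geometry$V_m_pancreas,
      I = wl * state[["NI_m_liver"]] / geometry$V_m_liver +
        wp * state[["NI_m_pancreas"]] / geometry$V_m_pancreas)
  }
}

#' Initial model state for a dosed co-culture
#'
#' Applies the day-1 exchange: glucose amounts are
#' `(G_dose + dG_d1) * V_m` and insulin amounts `dI_d1 * V_m` per
#' compartment; `t_state = 0`, `G_int = 0`, `G_slow_pancreas = 5.5`
#' mmol/L and `V_beta_islets = V_beta_0`.
#'
#' @param params an [mps_parameters()] object.
#' @param G_dose dosed glucose concentration (mmol/L), nonnegative.
#' @return Named state vector, see [model_state()].
#' @export
initial_state <- function(params, G_dose) {
  if (G_dose < 0) stop("G_dose must be nonnegative")
  g <- params$geometry; o <- params$offsets
  model_state(
    NG_m_liver = (G_dose + o$dG_d1) * g$V_m_liver,
    NG_m_pancreas = (G_dose + o$dG_d1) * g$V_m_pancreas,
    NI_m_liver = o$dI_d1 * g$V_m_liver,
    NI_m_pancreas = o$dI_d1 * g$V_m_pancreas,
    G_int = 0, G_slow_pancreas = 5.5,
    V_beta_islets = params$slow$V_beta_0, t_state = 0)
}
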