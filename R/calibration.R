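# SEM preprocessing, weighted least-squares cost, chi-squared acceptance,
# the simulated-annealing acceptable-set search, and envelope prediction.

#' Preprocess SEM values of a GTT dataset
#'
#' With only 2-6 replicate circuits the measured standard errors
#' underestimate the true uncertainty. Two corrections are applied, in
#' order: (1) SEM floor - any SEM below 5% of the corresponding mean is
#' replaced by the largest measured SEM across all points of the dataset
#' (per condition; optionally per signal); (2) exchange-offset
#' inflation - for every GTT window, the magnitude of the measured t = 0
#' deviation from the nominal dosed concentration is added to the SEM of
#' every point of that window and signal.
#'
#' @param data GTT data frame with columns `condition`, `signal`
#'   (`"glucose"`/`"insulin"`), `time_h`, `mean`, `sem`, `n`,
#'   `gtt_window`.
#' @param nominal nominal dosed concentration at the start of each GTT
#'   window: either a named vector `c(glucose = , insulin = )` applied to
#'   all windows, or a data frame with columns `gtt_window`, `signal`,
#'   `nominal` (e.g. to give the spiked window a nonzero insulin
#'   nominal).
#' @param per_signal take the SEM-floor replacement value per signal
#'   instead of across the whole dataset (default `FALSE`).
#' @return The data frame with corrected `sem` and attribute
#'   `preprocessed = TRUE`.
#' @export
preprocess_sem <- function(data, nominal = c(glucose = 11, insulin = 0),
                           per_signal = FALSE) {
  .check_gtt_columns(data)
  if (all(data$sem == 0))
    stop("all SEM values are zero: floor replacement undefined")
  .nominal_for <- function(window, signal) {
    if (is.data.frame(nominal)) {
      hit <- nominal$gtt_window == window & nominal$signal == signal
      if (!any(hit))
        stop(sprintf("no nominal concentration for window '%s', signal '%s'",
                     window, signal))
      nominal$nominal[hit][1]
    } else nominal[[signal]]
  }
  out <- split(data, data$condition)
  out <- lapply(out, function(d) {
    raw_sem <- d$sem
    for (sig in unique(d$signal)) {
      rows <- d$signal == sig
      ceiling_sem <- if (per_signal) max(raw_sem[rows]) else max(raw_sem)
      # a zero SEM (e.g. an exactly-zero measured mean) is always
      # unrealistic: it would give the residual infinite weight
      low <- rows & (raw_sem < 0.05 * abs(d$mean) | raw_sem == 0)
      d$sem[low] <- ceiling_sem
    }
    for (w in unique(d$gtt_window)) {
      for (sig in unique(d$signal)) {
        rows <- d$gtt_window == w & d$signal == sig
        if (!any(rows)) next
        t0 <- min(d$time_h[rows])
        m0 <- d$mean[rows & d$time_h == t0][1]
        offset <- abs(m0 - .nominal_for(w, sig))
        d$sem[rows] <- d$sem[rows] + offset
      }
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "preprocessed") <- TRUE
  out
}

.check_gtt_columns <- function(data) {
  need <- c("condition", "signal", "time_h", "mean", "sem", "n",
            "gtt_window")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop(sprintf("missing GTT column(s): %s", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(data$signal), c("glucose", "insulin"))
  if (length(bad))
    stop(sprintf("unknown signal(s): %s", paste(bad, collapse = ", ")))
  invisible(data)
}

#' Weighted least-squares cost of a parameter set
#'
#' The calibration cost is the sum over all signals and time points of the
#' squared residuals between observed pooled means and simulated pooled
#' observables, weighted by the (preprocessed) squared SEM:
#' \deqn{V(p) = \sum_i \sum_t (y_i(t) - \hat y_i(t, p))^2 / SEM_i(t)^2.}
#'
#' @param params an [mps_parameters()] object.
#' @param data preprocessed GTT data frame (see [preprocess_sem()]); rows
#'   are matched to simulated samples by condition, GTT window and time.
#' @param protocols a named list of [mps_protocol()] objects, one per
#'   condition in `data` (a single unnamed protocol is accepted when the
#'   data hold one condition).
#' @param solver a [solver_config()].
#' @return The scalar cost (dimensionless).
#' @export
gtt_cost <- function(params, data, protocols, solver = solver_config()) {
  .check_gtt_columns(data)
  if (any(data$sem <= 0)) stop("cost requires strictly positive SEMs")
  if (inherits(protocols, "mps_protocol"))
    protocols <- setNames(list(protocols), unique(data$condition)[1])
  total <- 0
  for (cond in unique(data$condition)) {
    if (is.null(protocols[[cond]]))
      stop(sprintf("no protocol supplied for condition '%s'", cond))
    sim <- simulate_protocol(params, protocols[[cond]], solver)
    d <- data[data$condition == cond, ]
    key_sim <- paste(sim$samples$window, signif(sim$samples$time, 10))
    key_dat <- paste(d$gtt_window, signif(d$time_h, 10))
    idx <- match(key_dat, key_sim)
    if (anyNA(idx))
      stop(sprintf("no simulated sample for condition '%s' at %s",
                   cond, paste(key_dat[is.na(idx)], collapse = "; ")))
    pred <- ifelse(d$signal == "glucose", sim$samples$glucose[idx],
                   sim$samples$insulin[idx])
    total <- total + sum(((d$mean - pred) / d$sem)^2)
  }
  total
}

#' Chi-squared rejection threshold
#'
#' The (1 - alpha) quantile of the chi-squared distribution used to gate
#' acceptable parameter sets; by convention the degrees of freedom equal
#' the number of residual data points.
#'
#' @param df degrees of freedom (positive integer).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return The threshold value.
#' @examples
#' chi2_threshold(25) # 37.65
#' chi2_threshold(6)  # 12.59
#' @export
chi2_threshold <- function(df, alpha = 0.05) {
  if (length(df) != 1 || !is.finite(df) || df < 1 || df != round(df))
    stop("df must be a positive integer")
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  qchisq(1 - alpha, df = df)
}

#' Search configuration for the acceptable-set fitter
#'
#' @param n_restarts number of independent annealing restarts.
#' @param n_iter cost evaluations per restart.
#' @param T0 initial temperature; default is the initial cost of the
#'   restart (scales acceptance to the problem).
#' @param cooling geometric cooling factor, \eqn{T_k = T_0 c^k}.
#' @param step0 initial proposal step as a fraction of the (log-)range.
#' @param seed RNG seed recorded in the ensemble.
#' @param polish run a Nelder-Mead refinement from the best annealing
#'   point (its evaluations also feed the acceptable set).
#' @param polish_maxit Nelder-Mead iteration cap.
#' @return A list of class `search_config`.
#' @export
search_config <- function(n_restarts = 5, n_iter = 2000, T0 = NULL,
                          cooling = 0.95, step0 = 1, seed = 1,
                          polish = TRUE, polish_maxit = 200) {
  structure(list(n_restarts = n_restarts, n_iter = n_iter, T0 = T0,
                 cooling = cooling, step0 = step0, seed = seed,
                 polish = polish, polish_maxit = polish_maxit),
            class = "search_config")
}

#' Free-parameter bounds
#'
#' Builds the bounds table for the fitter. Built-in defaults cover the
#' shipped presets: `{S_I0, I_max_Si, EC50_Si, sigma_max, alpha, offsets}`
#' for H1 plus `{I_max_additional, EC50_additional}` for H2. Parameters
#' with a strictly positive lower bound are searched on a log scale.
#'
#' @param names character vector of free equation symbols, or one of the
#'   presets `"H1"` / `"H2"` / `"baseline"` (the low-hydrocortisone
#'   two-parameter set `{S_I0, sigma_max}`).
#' @param lower,upper optional numeric vectors overriding the default
#'   bounds (recycled against `names`).
#' @return Data frame with columns `name`, `lower`, `upper`.
#' @export
free_parameters <- function(names, lower = NULL, upper = NULL) {
  defaults <- list(
    S_I0 = c(1e-4, 1), I_max_Si = c(0, 1), EC50_Si = c(1, 5000),
    sigma_max = c(1e3, 1e7), alpha = c(100, 1e6), E_G0 = c(0.01, 10),
    EC50_I = c(0.5, 50), k_elimination_I_spheroids = c(0.1, 100),
    I_max_additional = c(0, 1), EC50_additional = c(10, 2000),
    dG_d1 = c(-3, 3), dG_d13 = c(-3, 3), dI_d1 = c(0, 50),
    dI_d13 = c(0, 50))
  if (length(names) == 1 && names %in% c("H1", "H2", "baseline")) {
    names <- switch(names,
      baseline = c("S_I0", "sigma_max"),
      H1 = c("S_I0", "I_max_Si", "EC50_Si", "sigma_max", "alpha",
             "dG_d1", "dG_d13", "dI_d1", "dI_d13"),
      H2 = c("S_I0", "I_max_Si", "EC50_Si", "sigma_max", "alpha",
             "I_max_additional", "EC50_additional",
             "dG_d1", "dG_d13", "dI_d1", "dI_d13"))
  }
  miss <- setdiff(names, base::names(defaults))
  if (is.null(lower) && length(miss))
    stop(sprintf("no default bounds for: %s; supply lower/upper",
                 paste(miss, collapse = ", ")))
  lo <- if (is.null(lower)) vapply(names, function(n) defaults[[n]][1],
                                   numeric(1)) else rep_len(lower, length(names))
  hi <- if (is.null(upper)) vapply(names, function(n) defaults[[n]][2],
                                   numeric(1)) else rep_len(upper, length(names))
  if (any(hi <= lo)) stop("upper bounds must exceed lower bounds")
  data.frame(name = names, lower = unname(lo), upper = unname(hi),
             stringsAsFactors = FALSE)
}

# internal transforms between natural and search scale
.to_search <- function(x, free) ifelse(free$lower > 0, log(x), x)
.from_search <- function(u, free) ifelse(free$lower > 0, exp(u), u)
.clip <- function(x, free) pmin(pmax(x, free$lower), free$upper)

#' Fit the model and collect the acceptable parameter set
#'
#' Seeded simulated annealing (multiple restarts, geometric cooling,
#' log-scale proposals for positive parameters) minimising [gtt_cost()],
#' followed by an optional Nelder-Mead polish. Every cost evaluation -
#' not only accepted annealing moves - whose cost passes the chi-squared
#' threshold is recorded into the acceptable set, which is the model's
#' uncertainty representation used by [predict_envelope()] and
#' [test_hypothesis()].
#'
#' @param base_params an [mps_parameters()] object holding every fixed
#'   parameter and the hypothesis; free parameters are overridden during
#'   the search.
#' @param data preprocessed GTT data frame.
#' @param protocols named list of protocols, see [gtt_cost()].
#' @param free bounds table from [free_parameters()].
#' @param config a [search_config()].
#' @param alpha chi-squared significance level (default 0.05).
#' @param df degrees of freedom for the threshold; defaults to the number
#'   of residual data points.
#' @param solver a [solver_config()].
#' @return An object of class `mps_ensemble`: acceptable parameter matrix
#'   (`par`, one row per recorded vector), their `cost`s, the `best`
#'   index, `threshold`, `df`, the `free` table, the `base` parameters,
#'   search metadata, and `flagged = TRUE` when no point passed the
#'   threshold (then `best_par`/`best_cost` carry the best found vector).
#' @export
fit_ensemble <- function(base_params, data, protocols, free,
                         config = search_config(), alpha = 0.05,
                         df = NULL, solver = solver_config()) {
  stopifnot(inherits(base_params, "mps_parameters"), is.data.frame(free))
  if (is.null(df)) df <- nrow(data)
  threshold <- chi2_threshold(df, alpha)
  n_free <- nrow(free)

  rec_par <- list(); rec_cost <- numeric(0)
  n_eval <- 0L
  best_x <- NULL; best_fx <- Inf
  costfun <- function(x) {
    x <- .clip(x, free)
    fx <- gtt_cost(update_parameters(base_params, setNames(x, free$name)),
                   data, protocols, solver)
    n_eval <<- n_eval + 1L
    if (is.finite(fx) && fx <= threshold) {
      rec_par[[length(rec_par) + 1L]] <<- x
      rec_cost[length(rec_cost) + 1L] <<- fx
    }
    if (fx < best_fx) { best_fx <<- fx; best_x <<- x }
    fx
  }

  set.seed(config$seed)
  start_vals <- tryCatch(.clip(parameter_values(base_params, free$name), free),
                         error = function(e) NULL)
  lo_s <- .to_search(free$lower, free); hi_s <- .to_search(free$upper, free)

  for (r in seq_len(config$n_restarts)) {
    u <- if (r == 1 && !is.null(start_vals)) .to_search(start_vals, free)
         else runif(n_free, lo_s, hi_s)  # log-uniform for positive params
    x <- .clip(.from_search(u, free), free)
    fx <- costfun(x)
    T0 <- config$T0 %||% max(fx, threshold, 1e-6)
    for (k in seq_len(config$n_iter - 1)) {
      Tk <- T0 * config$cooling^k
      frac <- max(config$cooling^k, 0.02)
      u_prop <- u + runif(n_free, -1, 1) * config$step0 * frac *
        (hi_s - lo_s)
      u_prop <- pmin(pmax(u_prop, lo_s), hi_s)
      x_prop <- .from_search(u_prop, free)
      fx_prop <- costfun(x_prop)
      if (fx_prop < fx ||
          runif(1) < exp(-(fx_prop - fx) / max(Tk, 1e-12))) {
        u <- u_prop; x <- x_prop; fx <- fx_prop
      }
    }
  }

  if (config$polish && !is.null(best_x)) {
    u0 <- .to_search(.clip(best_x, free), free)
    fn <- function(u) costfun(.from_search(pmin(pmax(u, lo_s), hi_s), free))
    if (n_free == 1) {
      optim(u0, fn, method = "Brent", lower = lo_s, upper = hi_s,
            control = list(maxit = config$polish_maxit))
    } else {
      optim(u0, fn, method = "Nelder-Mead",
            control = list(maxit = config$polish_maxit, reltol = 1e-10))
    }
  }

  par <- if (length(rec_par)) do.call(rbind, rec_par) else
    matrix(numeric(0), ncol = n_free)
  colnames(par) <- free$name
  flagged <- nrow(par) == 0
  structure(list(par = par, cost = rec_cost,
                 best = if (!flagged) which.min(rec_cost) else NA_integer_,
                 threshold = threshold, df = df, alpha = alpha,
                 free = free, base = base_params, seed = config$seed,
                 n_eval = n_eval, flagged = flagged,
                 best_par = setNames(best_x, free$name),
                 best_cost = best_fx),
            class = "mps_ensemble")
}

#' @export
print.mps_ensemble <- function(x, ...) {
  cat(sprintf(
    "<mps_ensemble> %s: %d acceptable of %d evaluations (chi2 threshold %.2f, df %d)\n",
    x$base$hypothesis, nrow(x$par), x$n_eval, x$threshold, x$df))
  cat(sprintf("  best cost %.3f%s\n", x$best_cost,
              if (x$flagged) " [FLAGGED: no acceptable point]" else ""))
  invisible(x)
}

#' Number of acceptable parameter vectors in an ensemble
#' @param ensemble an `mps_ensemble`.
#' @return Integer count.
#' @export
ensemble_size <- function(ensemble) nrow(ensemble$par)

#' Materialise one ensemble member as a full parameter object
#'
#' @param ensemble an `mps_ensemble`.
#' @param i member row index, or `"best"` (default). For a flagged
#'   ensemble `"best"` falls back to the best-found (non-acceptable)
#'   vector.
#' @return An [mps_parameters()] object.
#' @export
ensemble_parameters <- function(ensemble, i = "best") {
  if (identical(i, "best")) {
    if (ensemble$flagged)
      return(update_parameters(ensemble$base, ensemble$best_par))
    i <- ensemble$best
  }
  update_parameters(ensemble$base,
                    setNames(ensemble$par[i, ], colnames(ensemble$par)))
}

#' Prediction uncertainty envelope
#'
#' Simulates the protocol for the optimal member plus, for each free
#' parameter, the ensemble members attaining its minimum and maximum
#' (2 x n_free + 1 simulations), and returns the pointwise minimum and
#' maximum of the pooled observables across these trajectories. With
#' `members = "all"` every acceptable member is simulated instead.
#'
#' @param ensemble a non-flagged `mps_ensemble`.
#' @param protocol an [mps_protocol()].
#' @param members `"extremes"` (default, the per-parameter-extreme
#'   scheme) or `"all"`.
#' @param solver a [solver_config()].
#' @return An object of class `mps_envelope`: data frame with columns
#'   `time`, `window`, `signal`, `lower`, `central`, `upper`.
#' @export
predict_envelope <- function(ensemble, protocol,
                             members = c("extremes", "all"),
                             solver = solver_config()) {
  members <- match.arg(members)
  if (ensemble$flagged || ensemble_size(ensemble) == 0)
    stop("cannot build an envelope from an empty acceptable set")
  idx <- if (members == "all") seq_len(ensemble_size(ensemble)) else
    unique(c(ensemble$best,
             as.vector(apply(ensemble$par, 2, which.min)),
             as.vector(apply(ensemble$par, 2, which.max))))
  sims <- lapply(idx, function(i)
    simulate_protocol(ensemble_parameters(ensemble, i), protocol, solver))
  central <- simulate_protocol(ensemble_parameters(ensemble, "best"),
                               protocol, solver)
  gmat <- vapply(sims, function(s) s$samples$glucose,
                 numeric(nrow(central$samples)))
  imat <- vapply(sims, function(s) s$samples$insulin,
                 numeric(nrow(central$samples)))
  if (is.null(dim(gmat))) { gmat <- rbind(gmat); imat <- rbind(imat) }
  s <- central$samples
  env <- rbind(
    data.frame(time = s$time, window = s$window, signal = "glucose",
               lower = apply(gmat, 1, min),
               central = s$glucose,
               upper = apply(gmat, 1, max), stringsAsFactors = FALSE),
    data.frame(time = s$time, window = s$window, signal = "insulin",
               lower = apply(imat, 1, min),
               central = s$insulin,
               upper = apply(imat, 1, max), stringsAsFactors = FALSE))
  # the optimum is among the simulated members, so lower <= central <= upper
  structure(env, class = c("mps_envelope", "data.frame"),
            members = idx, hypothesis = ensemble$base$hypothesis)
}
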