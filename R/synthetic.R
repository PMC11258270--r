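# Synthetic-study generators: GTT studies with replicate circuits and
# SEM-style noise, and nested-variance endpoint matrices. These provide
# the statistical structure the calibration and reproducibility analyses
# assume, so the whole pipeline is testable without measured chip data.

#' Design of a synthetic GTT study
#'
#' @param conditions named numeric vector of maintenance glucose levels
#'   (mmol/L) per condition arm, e.g. `c(hyper = 11, normo = 5.5)`.
#' @param n_circuits replicate circuits per condition (>= 2).
#' @param noise_cv coefficient of variation of the multiplicative
#'   Gaussian measurement noise applied to each sampled concentration
#'   (default 0.10, emulating assay CV); `0` gives noiseless replicates.
#' @param noise_model `"multiplicative"` (CV-style, default) or
#'   `"absolute"` (constant standard deviation `noise_sd`).
#' @param noise_sd absolute noise sd (used when
#'   `noise_model = "absolute"`): `c(glucose = , insulin = )`.
#' @param gtt_days co-culture days on which GTT windows start.
#' @param duration_days nominal study length (day 1 to `duration_days`).
#' @param spike_insulin insulin dose (mIU/L) added at the final GTT
#'   exchange.
#' @param donor_effect multipliers on `S_I0` and `sigma_max` emulating
#'   donor-dependent variation (the two constants re-calibrated per
#'   donor).
#' @param seed RNG seed; the generated study is fully reproducible.
#' @return A list of class `study_design`.
#' @export
study_design <- function(conditions = c(hyper = 11, normo = 5.5),
                         n_circuits = 3, noise_cv = 0.10,
                         noise_model = c("multiplicative", "absolute"),
                         noise_sd = c(glucose = 0.5, insulin = 2),
                         gtt_days = c(1, 7, 13), duration_days = 15,
                         spike_insulin = 0,
                         donor_effect = c(S_I0 = 1, sigma_max = 1),
                         seed = 1) {
  noise_model <- match.arg(noise_model)
  if (n_circuits < 2) stop("n_circuits must be >= 2")
  if (noise_cv < 0 || any(noise_sd < 0))
    stop("noise parameters must be nonnegative")
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("conditions must be a named vector of glucose levels")
  structure(list(conditions = conditions, n_circuits = n_circuits,
                 noise_cv = noise_cv, noise_model = noise_model,
                 noise_sd = noise_sd, gtt_days = gtt_days,
                 duration_days = duration_days,
                 spike_insulin = spike_insulin,
                 donor_effect = donor_effect, seed = seed),
            class = "study_design")
}

#' Seal / unseal a ground-truth record
#'
#' Generated studies carry their ground truth in a sealed record so
#' pipeline code cannot read it by accident; recovery-scoring code must
#' opt in explicitly with `unseal()`.
#'
#' @param x the object to seal, or a `sealed_truth` to open.
#' @return `seal()` returns a `sealed_truth`; `unseal()` its contents.
#' @export
seal <- function(x) structure(list(contents = x), class = "sealed_truth")

#' @rdname seal
#' @export
unseal <- function(x) {
  stopifnot(inherits(x, "sealed_truth"))
  x$contents
}

#' @export
print.sealed_truth <- function(x, ...) {
  cat("<sealed_truth> ground-truth record; use unseal() to read\n")
  invisible(x)
}

#' Generate a synthetic GTT study
#'
#' Simulates each condition's protocol with the true parameters (donor
#' multipliers applied to `S_I0` and `sigma_max`), draws `n_circuits`
#' noisy replicate curves with independent multiplicative Gaussian noise
#' per sampled concentration (truncated at zero with a logged count),
#' and emits the per-timepoint mean/SEM table in the calibration input
#' format, plus a sealed ground-truth record.
#'
#' @param true_params an [mps_parameters()] object (before donor
#'   multipliers).
#' @param design a [study_design()].
#' @param solver a [solver_config()].
#' @return A list of class `mps_study`: `data` (GTT table: `condition`,
#'   `signal`, `time_h`, `mean`, `sem`, `n`, `gtt_window`), `replicates`
#'   (long per-circuit draws), `protocols` (named per condition),
#'   `truth` (sealed record with the effective parameters and noiseless
#'   curves), `n_truncated`.
#' @export
generate_gtt_study <- function(true_params, design,
                               solver = solver_config()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  eff <- update_parameters(true_params, c(
    S_I0 = true_params$fast$S_I0 * design$donor_effect[["S_I0"]],
    sigma_max = true_params$fast$sigma_max *
      design$donor_effect[["sigma_max"]]))
  n_trunc <- 0L
  data_rows <- list(); rep_rows <- list(); curves <- list()
  protocols <- lapply(design$conditions, function(gl)
    gtt_protocol(maintenance_glucose = gl,
                 gtt_days = design$gtt_days,
                 duration_days = design$duration_days,
                 spike_insulin = design$spike_insulin))
  names(protocols) <- names(design$conditions)
  for (cond in names(design$conditions)) {
    sim <- simulate_protocol(eff, protocols[[cond]], solver)
    s <- sim$samples
    curves[[cond]] <- s
    for (sig in c("glucose", "insulin")) {
      truth <- if (sig == "glucose") s$glucose else s$insulin
      draws <- vapply(seq_len(design$n_circuits), function(r) {
        noisy <- if (design$noise_model == "multiplicative")
          truth * (1 + design$noise_cv * rnorm(length(truth)))
        else truth + design$noise_sd[[sig]] * rnorm(length(truth))
        n_trunc <<- n_trunc + sum(noisy < 0)
        pmax(noisy, 0)
      }, numeric(length(truth)))
      if (is.null(dim(draws))) draws <- rbind(draws)
      data_rows[[length(data_rows) + 1L]] <- data.frame(
        condition = cond, signal = sig, time_h = s$time,
        mean = rowMeans(draws),
        sem = apply(draws, 1, sd) / sqrt(design$n_circuits),
        n = design$n_circuits, gtt_window = s$window,
        stringsAsFactors = FALSE)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        condition = cond, signal = sig,
        circuit = rep(seq_len(design$n_circuits), each = length(truth)),
        time_h = rep(s$time, design$n_circuits),
        gtt_window = rep(s$window, design$n_circuits),
        value = as.vector(draws), stringsAsFactors = FALSE)
    }
  }
  if (n_trunc > 0)
    message(sprintf("generate_gtt_study: %d draws truncated at 0", n_trunc))
  structure(list(data = do.call(rbind, data_rows),
                 replicates = do.call(rbind, rep_rows),
                 protocols = protocols,
                 truth = seal(list(params = eff, curves = curves,
                                   design = design)),
                 n_truncated = n_trunc),
            class = "mps_study")
}

#' @export
print.mps_study <- function(x, ...) {
  cat(sprintf("<mps_study> %d conditions, %d data rows (truth sealed)\n",
              length(x$protocols), nrow(x$data)))
  invisible(x)
}

#' Generate endpoint matrices with nested variance components
#'
#' Draws nested random effects (laboratory, study-within-lab,
#' circuit-within-study) plus residual noise around a per-timepoint
#' trend, emulating the variance structure of multi-site chip studies.
#'
#' @param components named numeric vector of variance components (on the
#'   endpoint scale): `lab`, `study`, `circuit`, `residual`.
#' @param n_labs,n_studies,n_circuits nesting sizes (`n_studies` per
#'   lab, `n_circuits` per study).
#' @param trend per-timepoint mean endpoint values; a flat trend (the
#'   default) makes target variance purely residual-driven.
#' @param seed RNG seed.
#' @return A list: `data` (long data frame `lab`, `study`, `circuit`,
#'   `timepoint`, `value`) and `matrices` (one circuit-by-timepoint
#'   matrix per lab/study combination).
#' @export
generate_endpoint_matrix <- function(components = c(lab = 0, study = 0,
                                                    circuit = 0.5,
                                                    residual = 1),
                                     n_labs = 1, n_studies = 1,
                                     n_circuits = 4,
                                     trend = rep(10, 7), seed = 1) {
  if (any(components < 0)) stop("variance components must be nonnegative")
  need <- c("lab", "study", "circuit", "residual")
  stopifnot(all(need %in% names(components)))
  set.seed(seed)
  n_t <- length(trend)
  rows <- list()
  for (l in seq_len(n_labs)) {
    e_lab <- rnorm(1, 0, sqrt(components[["lab"]]))
    for (s in seq_len(n_studies)) {
      e_study <- rnorm(1, 0, sqrt(components[["study"]]))
      for (ci in seq_len(n_circuits)) {
        e_circ <- rnorm(1, 0, sqrt(components[["circuit"]]))
        vals <- trend + e_lab + e_study + e_circ +
          rnorm(n_t, 0, sqrt(components[["residual"]]))
        rows[[length(rows) + 1L]] <- data.frame(
          lab = sprintf("lab%d", l), study = sprintf("study%d", s),
          circuit = sprintf("c%d", ci), timepoint = seq_len(n_t),
          value = vals, stringsAsFactors = FALSE)
      }
    }
  }
  data <- do.call(rbind, rows)
  key <- interaction(data$lab, data$study, drop = TRUE)
  matrices <- lapply(split(data, key), endpoint_matrix)
  list(data = data, matrices = matrices)
}
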