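# Parameter containers for the pancreas-liver MPS model.
#
# Units are fixed throughout the package: time in hours, volumes in litres,
# glucose amounts in mmol (concentrations mmol/L), insulin amounts in mIU
# (concentrations mIU/L). Unit conversions happen at I/O boundaries only.

.GEOMETRY_FIELDS <- c("V_m_liver", "V_m_pancreas", "V_HepaRG_spheroids",
                      "Q", "V_sample_liver", "V_sample_pancreas")
.FAST_FIELDS <- c("E_G0", "S_I0", "I_max_Si", "EC50_Si", "EGP", "sigma_max",
                  "alpha", "EC50_I", "k_elimination_I_spheroids", "G_normo")
.SLOW_FIELDS <- c("k_v", "d_0", "r1", "r2", "tau_slow", "V_beta_0")
.H2_FIELDS <- c("I_max_additional", "EC50_additional")
.OFFSET_FIELDS <- c("dG_d1", "dG_d13", "dI_d1", "dI_d13")

.HYPOTHESES <- c(H1 = 1L, H2 = 2L, LOW_HCT = 3L)

#' Chip geometry of the pancreas-liver MPS
#'
#' Compartment and sampling volumes plus the inter-compartment flow rate of
#' the two-circuit chip. Defaults reflect the platform: 300 ul of co-culture
#' medium per compartment, 15 ul supernatant draws, and a mean pump flow of
#' 4.94 ul/min between the compartments.
#'
#' @param V_m_liver,V_m_pancreas medium volume per compartment (L).
#' @param V_HepaRG_spheroids total HepaRG cell volume in the liver
#'   compartment (L). Default assumes 40 spheroids of 24,000 hepatocytes at
#'   ~2.5 pL per cell.
#' @param Q inter-compartment flow rate (L/h); default 4.94 ul/min.
#' @param V_sample_liver,V_sample_pancreas sampled medium volume per GTT
#'   draw and compartment (L).
#' @return An object of class `mps_geometry` (named list).
#' @export
mps_geometry <- function(V_m_liver = 300e-6,
                         V_m_pancreas = 300e-6,
                         V_HepaRG_spheroids = 2.4e-6,
                         Q = 4.94e-6 * 60,
                         V_sample_liver = 15e-6,
                         V_sample_pancreas = 15e-6) {
  g <- list(V_m_liver = V_m_liver, V_m_pancreas = V_m_pancreas,
            V_HepaRG_spheroids = V_HepaRG_spheroids, Q = Q,
            V_sample_liver = V_sample_liver,
            V_sample_pancreas = V_sample_pancreas)
  vals <- unlist(g)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry fields must be finite and strictly positive")
  structure(g, class = "mps_geometry")
}

#' Model parameters for the pancreas-liver MPS
#'
#' Single home of every symbol of the model equations, grouped into chip
#' geometry, fast (hours) kinetics, slow (weeks) beta-cell dynamics, the
#' two-factor-hypothesis (H2) block, and medium-exchange offset corrections.
#'
#' The hypothesis selects the structural variant:
#' * `"H1"` - insulin resistance driven by hyperglycemic exposure alone.
#' * `"H2"` - H1 plus an additional time-dependent diabetogenic factor on
#'   insulin sensitivity (requires the `h2` block).
#' * `"LOW_HCT"` - physiological-hydrocortisone variant: the additional
#'   factor is absent and secretion capacity is constant at `sigma_max`.
#'
#' @param geometry an [mps_geometry()] object.
#' @param fast named list of fast-model kinetic constants: `E_G0` (1/h),
#'   `S_I0` (L/mIU/h), `I_max_Si` (fraction in \[0,1\]), `EC50_Si`
#'   (mmol h/L), `EGP` (mmol/L/h, fixed 0 in this system), `sigma_max`
#'   (mIU/L/h per unit beta-cell volume), `alpha` (h^2), `EC50_I` (mmol/L),
#'   `k_elimination_I_spheroids` (1/h), `G_normo` (mmol/L, 5.5).
#' @param slow named list of beta-cell dynamics constants: `k_v`
#'   (dimensionless), `d_0` (1/h), `r1` (L/mmol/h), `r2` (L^2/mmol^2/h),
#'   `tau_slow` (h), `V_beta_0` (L, initial beta-cell volume).
#' @param h2 named list `I_max_additional` (fraction in \[0,1\]) and
#'   `EC50_additional` (h), or `NULL` unless `hypothesis = "H2"`.
#' @param offsets named list `dG_d1`, `dG_d13` (mmol/L), `dI_d1`, `dI_d13`
#'   (mIU/L): concentration offsets absorbing medium-exchange errors at the
#'   day-1 and day-13 exchanges.
#' @param hypothesis one of `"H1"`, `"H2"`, `"LOW_HCT"`.
#' @return An object of class `mps_parameters`.
#' @seealso [default_parameters()], [update_parameters()]
#' @export
mps_parameters <- function(geometry, fast, slow, h2 = NULL,
                           offsets = list(dG_d1 = 0, dG_d13 = 0,
                                          dI_d1 = 0, dI_d13 = 0),
                           hypothesis = c("H2", "H1", "LOW_HCT")) {
  hypothesis <- match.arg(hypothesis)
  p <- structure(list(geometry = geometry, fast = fast, slow = slow,
                      h2 = h2, offsets = offsets, hypothesis = hypothesis),
                 class = "mps_parameters")
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "mps_parameters"))
  if (!inherits(p$geometry, "mps_geometry"))
    stop("geometry must be an mps_geometry object")
  .need <- function(block, fields, label) {
    miss <- setdiff(fields, names(block))
    if (length(miss))
      stop(sprintf("missing %s field(s): %s", label,
                   paste(miss, collapse = ", ")))
    v <- unlist(block[fields])
    if (any(!is.finite(v)))
      stop(sprintf("non-finite %s parameter", label))
    v
  }
  fv <- .need(p$fast, .FAST_FIELDS, "fast")
  if (any(fv < 0)) stop("fast parameters must be nonnegative")
  if (p$fast$I_max_Si > 1) stop("I_max_Si must lie in [0, 1]")
  sv <- .need(p$slow, .SLOW_FIELDS, "slow")
  if (any(sv < 0)) stop("slow parameters must be nonnegative")
  ov <- .need(p$offsets, .OFFSET_FIELDS, "offset")
  if (p$offsets$dI_d1 < 0 || p$offsets$dI_d13 < 0)
    stop("insulin offsets must be nonnegative")
  if (p$hypothesis == "H2") {
    if (is.null(p$h2)) stop("hypothesis H2 requires an h2 block")
    hv <- .need(p$h2, .H2_FIELDS, "h2")
    if (any(hv < 0) || p$h2$I_max_additional > 1)
      stop("h2 parameters must be nonnegative with I_max_additional <= 1")
  } else if (!is.null(p$h2)) {
    stop("h2 block is only allowed for hypothesis H2")
  }
  invisible(p)
}

.default_param_cache <- new.env(parent = emptyenv())

#' Default model parameters
#'
#' Returns the package's default parameter set, read from the annotated
#' configuration file `system.file("extdata", "default_parameters.yaml",
#' package = "glucotwin")`. The kinetic values are documented assumptions
#' chosen to reproduce the qualitative on-chip GTT phenomenology (rapid
#' glucose disposal with an insulin response of tens of mIU/L early in
#' co-culture, progressively blunted under the diseased condition); every
#' value can be overridden.
#'
#' @param hypothesis structural variant, see [mps_parameters()].
#' @param ... named scalar overrides for any equation symbol, e.g.
#'   `default_parameters("H1", S_I0 = 0.02)`; passed to
#'   [update_parameters()].
#' @return An `mps_parameters` object.
#' @examples
#' p <- default_parameters("H2", sigma_max = 2e5)
#' p$fast$sigma_max
#' @export
default_parameters <- function(hypothesis = c("H2", "H1", "LOW_HCT"), ...) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(.default_param_cache$base)) {
    path <- system.file("extdata", "default_parameters.yaml",
                        package = "glucotwin")
    if (!nzchar(path)) stop("default parameter file not found")
    .default_param_cache$base <- yaml::read_yaml(path)
  }
  cfg <- .default_param_cache$base
  p <- mps_parameters(
    geometry = do.call(mps_geometry, cfg$geometry),
    fast = cfg$fast, slow = cfg$slow,
    h2 = if (hypothesis == "H2") cfg$h2 else NULL,
    offsets = cfg$offsets, hypothesis = hypothesis)
  over <- list(...)
  if (length(over))
    p <- update_parameters(p, unlist(over))
  p
}

#' Update parameters by equation symbol
#'
#' Sets individual model constants addressed by their flat symbol name
#' (e.g. `S_I0`, `sigma_max`, `dG_d13`), resolving the containing block
#' automatically. Used by the fitter to inject free-parameter vectors.
#'
#' @param params an `mps_parameters` object.
#' @param values named numeric vector of symbol values.
#' @return The updated, re-validated `mps_parameters` object.
#' @export
update_parameters <- function(params, values) {
  stopifnot(inherits(params, "mps_parameters"),
            is.numeric(values), !is.null(names(values)))
  for (nm in names(values)) {
    val <- unname(values[[nm]])
    if (nm %in% .FAST_FIELDS) params$fast[[nm]] <- val
    else if (nm %in% .SLOW_FIELDS) params$slow[[nm]] <- val
    else if (nm %in% .OFFSET_FIELDS) params$offsets[[nm]] <- val
    else if (nm %in% .H2_FIELDS) {
      if (params$hypothesis != "H2")
        stop(sprintf("parameter '%s' requires hypothesis H2", nm))
      params$h2[[nm]] <- val
    } else if (nm %in% .GEOMETRY_FIELDS) {
      params$geometry[[nm]] <- val
    } else stop(sprintf("unknown parameter symbol '%s'", nm))
  }
  validate_parameters(params)
  params
}

#' Extract parameters by equation symbol
#'
#' @param params an `mps_parameters` object.
#' @param names character vector of symbol names.
#' @return Named numeric vector.
#' @export
parameter_values <- function(params, names) {
  flat <- c(unclass(params$geometry), params$fast, params$slow,
            params$offsets, params$h2)
  miss <- setdiff(names, base::names(flat))
  if (length(miss))
    stop(sprintf("unknown parameter symbol(s): %s",
                 paste(miss, collapse = ", ")))
  vapply(names, function(n) flat[[n]], numeric(1))
}

# Flat numeric vector handed to the ODE solver (order shared with
# src/mps_model.c; do not reorder).
.parm_vector <- function(params, G_d = 0) {
  g <- params$geometry; f <- params$fast; s <- params$slow
  h2 <- params$h2
  c(g$V_m_liver, g$V_m_pancreas, g$V_HepaRG_spheroids, g$Q,
    f$E_G0, f$S_I0, f$I_max_Si, f$EC50_Si, f$EGP, f$sigma_max, f$alpha,
    f$EC50_I, f$k_elimination_I_spheroids, f$G_normo,
    s$k_v, s$d_0, s$r1, s$r2, s$tau_slow,
    if (is.null(h2)) c(0, 1) else c(h2$I_max_additional, h2$EC50_additional),
    .HYPOTHESES[[params$hypothesis]], G_d)
}

#' Convert an insulin concentration from nmol/L to mIU/L
#'
#' Doses in the chip protocols are specified in nM while the model works in
#' mIU/L; the conversion constant defaults to 1 mIU/L = 6.00 pmol/L.
#'
#' @param x concentration in nmol/L.
#' @param pmol_per_mIU pmol of insulin per mIU (default 6.00).
#' @return Concentration in mIU/L.
#' @examples
#' nM_to_mIU(24) # the spiked dose used on day 13
#' @export
nM_to_mIU <- function(x, pmol_per_mIU = 6) {
  stopifnot(is.numeric(x), pmol_per_mIU > 0)
  x * 1000 / pmol_per_mIU
}

#' Read or write model parameters as an annotated YAML file
#'
#' Parameters serialize to a flat-per-block YAML mapping mirroring the
#' equation symbols (`geometry`, `fast`, `slow`, `h2`, `offsets`,
#' `hypothesis`).
#'
#' @param path file path.
#' @return `read_parameters()` returns an `mps_parameters` object;
#'   `write_parameters()` invisibly returns `path`.
#' @export
read_parameters <- function(path) {
  cfg <- yaml::read_yaml(path)
  hyp <- cfg$hypothesis %||% "H2"
  mps_parameters(geometry = do.call(mps_geometry, cfg$geometry),
                 fast = cfg$fast, slow = cfg$slow,
                 h2 = if (hyp == "H2") cfg$h2 else NULL,
                 offsets = cfg$offsets, hypothesis = hyp)
}

#' @rdname read_parameters
#' @param params an `mps_parameters` object.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  out <- list(hypothesis = params$hypothesis,
              geometry = unclass(params$geometry), fast = params$fast,
              slow = params$slow, offsets = params$offsets)
  if (!is.null(params$h2)) out$h2 <- params$h2
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mps_parameters <- function(x, ...) {
  cat(sprintf("<mps_parameters> hypothesis %s\n", x$hypothesis))
  blocks <- list(geometry = unclass(x$geometry), fast = x$fast,
                 slow = x$slow, offsets = x$offsets, h2 = x$h2)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b)) next
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%.4g", names(b), unlist(b)),
                      collapse = ", ")))
  }
  invisible(x)
}
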