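# Plain-text tabular I/O and the pipeline driver. MPS data have no
# community-standard format, so the versioned column schema written by
# write_gtt_table() is the interchange contract.

.GTT_HEADER <- "# glucotwin-gtt-v1 units: time_h=h glucose=mmol/L insulin=mIU/L"

#' Read a GTT table from CSV
#'
#' Expects the versioned schema (`condition`, `signal`, `time_h`, `mean`,
#' `sem`, `n`, `gtt_window`); a leading `#` header line declaring units
#' is checked when present. Validation errors name the offending row.
#'
#' @param path CSV file path.
#' @return A validated GTT data frame.
#' @export
read_gtt_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  if (startsWith(first, "#") && grepl("units:", first)) {
    if (!grepl("time_h=h", first, fixed = TRUE) ||
        !grepl("glucose=mmol/L", first, fixed = TRUE) ||
        !grepl("insulin=mIU/L", first, fixed = TRUE))
      stop("unit declaration mismatch: expected time_h=h, glucose=mmol/L, insulin=mIU/L")
  }
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  .check_gtt_columns(d)
  bad_sem <- which(!is.finite(d$sem) | d$sem < 0)
  if (length(bad_sem))
    stop(sprintf("negative or non-finite SEM at data row %d",
                 bad_sem[1]))
  key <- paste(d$condition, d$signal, d$time_h, d$gtt_window)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (condition, signal, time) at data row %d",
                 dup[1]))
  d
}

#' @rdname read_gtt_table
#' @param data a GTT data frame.
#' @export
write_gtt_table <- function(data, path) {
  .check_gtt_columns(data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.GTT_HEADER, con)
  write.csv(data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic 32-bit polynomial hash of a deparsed object (run stamping)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run configuration
#'
#' @param data GTT data frame or path to a CSV readable by
#'   [read_gtt_table()].
#' @param protocols named list of [mps_protocol()] objects per condition.
#' @param hypotheses hypotheses to calibrate (subset of `"H1"`, `"H2"`).
#' @param validation_window GTT window label held out for validation
#'   (e.g. `"d13"`); `NULL` fits on everything and skips the test.
#' @param nominal,per_signal passed to [preprocess_sem()] (applied to the
#'   calibration and validation subsets separately: they are distinct
#'   experiments, so neither's SEM floor sees the other's data).
#' @param free named list of [free_parameters()] tables per hypothesis;
#'   defaults to the shipped presets.
#' @param search a [search_config()] (its seed governs all randomness).
#' @param alpha significance level.
#' @param params named list of base [mps_parameters()] per hypothesis;
#'   defaults to [default_parameters()].
#' @param solver a [solver_config()].
#' @param out_dir optional directory for result artifacts.
#' @return A validated `run_config` list.
#' @export
run_config <- function(data, protocols, hypotheses = c("H1", "H2"),
                       validation_window = NULL,
                       nominal = c(glucose = 11, insulin = 0),
                       per_signal = FALSE,
                       free = NULL, search = search_config(),
                       alpha = 0.05, params = NULL,
                       solver = solver_config(), out_dir = NULL) {
  if (is.character(data) && !file.exists(data))
    stop(sprintf("data file not found: %s", data))
  hypotheses <- match.arg(hypotheses, several.ok = TRUE)
  structure(list(data = data, protocols = protocols,
                 hypotheses = hypotheses,
                 validation_window = validation_window, nominal = nominal,
                 per_signal = per_signal,
                 free = free, search = search, alpha = alpha,
                 params = params, solver = solver, out_dir = out_dir),
            class = "run_config")
}

#' Run the calibration / hypothesis-testing pipeline
#'
#' Executes preprocess -> fit (per hypothesis) -> validate (when a
#' validation window is held out), with structured stage logging. Every
#' artifact is stamped with the configuration hash, seed, and package
#' version; a stage failure aborts with the failing stage named.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage logging.
#' @return A result bundle (class `mps_run`): preprocessed `data`,
#'   `ensembles` and `verdicts` per hypothesis, and the `stamp`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stamp <- list(config_hash = .config_hash(config[c("hypotheses",
                                                    "validation_window",
                                                    "alpha")]),
                seed = config$search$seed,
                package_version = as.character(packageVersion("glucotwin")))
  t_start <- proc.time()[["elapsed"]]
  log_stage <- function(stage, ...) {
    if (!quiet)
      message(sprintf("[%s] %.1fs seed=%d %s", stage,
                      proc.time()[["elapsed"]] - t_start, stamp$seed,
                      sprintf(...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  data <- run_stage("read", {
    if (is.character(config$data)) read_gtt_table(config$data)
    else { .check_gtt_columns(config$data); config$data }
  })
  # calibration and validation are distinct experiments: split first so
  # each is preprocessed on its own (the SEM floor of the calibration
  # data must not see the later validation measurements)
  if (!is.null(config$validation_window)) {
    calib <- data[data$gtt_window != config$validation_window, ]
    valid <- data[data$gtt_window == config$validation_window, ]
    if (!nrow(valid))
      stop(sprintf("pipeline stage 'split' failed: no rows in validation window '%s'",
                   config$validation_window), call. = FALSE)
    valid <- run_stage("preprocess",
                       preprocess_sem(valid, nominal = config$nominal,
                                      per_signal = config$per_signal))
  } else { calib <- data; valid <- NULL }
  calib <- run_stage("preprocess",
                     preprocess_sem(calib, nominal = config$nominal,
                                    per_signal = config$per_signal))
  data <- if (is.null(valid)) calib else rbind(calib, valid)
  log_stage("preprocess", "%d data rows", nrow(data))

  ensembles <- list(); verdicts <- list()
  for (hyp in config$hypotheses) {
    base <- config$params[[hyp]] %||% default_parameters(hyp)
    free <- config$free[[hyp]] %||% free_parameters(hyp)
    ens <- run_stage(paste0("fit-", hyp),
                     fit_ensemble(base, calib, config$protocols, free,
                                  config = config$search,
                                  alpha = config$alpha,
                                  solver = config$solver))
    log_stage(paste0("fit-", hyp), "best cost %.2f, %d acceptable",
              ens$best_cost, ensemble_size(ens))
    ensembles[[hyp]] <- ens
    if (!is.null(valid) && ensemble_size(ens) > 0) {
      v <- run_stage(paste0("validate-", hyp),
                     test_hypothesis(ens, valid, config$protocols,
                                     alpha = config$alpha,
                                     solver = config$solver))
      log_stage(paste0("validate-", hyp), "%s (cost %.2f vs %.2f)",
                v$verdict, v$min_cost, v$threshold)
      verdicts[[hyp]] <- v
    }
  }

  result <- structure(list(data = data, ensembles = ensembles,
                           verdicts = verdicts, stamp = stamp),
                      class = "mps_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gtt_table(data, file.path(config$out_dir, "preprocessed.csv"))
    summary_rows <- do.call(rbind, lapply(names(ensembles), function(h) {
      e <- ensembles[[h]]
      v <- verdicts[[h]]
      data.frame(hypothesis = h, best_cost = e$best_cost,
                 n_acceptable = ensemble_size(e), threshold = e$threshold,
                 verdict = if (is.null(v)) NA_character_ else v$verdict,
                 validation_cost = if (is.null(v)) NA_real_ else v$min_cost,
                 seed = stamp$seed, config_hash = stamp$config_hash,
                 package_version = stamp$package_version,
                 stringsAsFactors = FALSE)
    }))
    write.csv(summary_rows, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
  }
  result
}

#' @export
print.mps_run <- function(x, ...) {
  cat(sprintf("<mps_run> hash %s, seed %d\n", x$stamp$config_hash,
              x$stamp$seed))
  for (h in names(x$ensembles)) {
    v <- x$verdicts[[h]]
    cat(sprintf("  %s: best cost %.2f, %d acceptable%s\n", h,
                x$ensembles[[h]]$best_cost,
                ensemble_size(x$ensembles[[h]]),
                if (is.null(v)) "" else sprintf(", validation %s", v$verdict)))
  }
  invisible(x)
}

#' Read or write a protocol as a structured YAML file
#'
#' Serializes the event list (times, kinds, concentrations, offset
#' flags), sampling schedule, duration and label.
#'
#' @param path file path.
#' @return `read_protocol()` returns an [mps_protocol()];
#'   `write_protocol()` invisibly returns `path`.
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  events <- do.call(rbind, lapply(cfg$events, function(e)
    protocol_event(e$time, e$kind, e$glucose_conc %||% 0,
                   e$insulin_conc %||% 0, e$applies_offsets %||% "none")))
  sampling <- do.call(rbind, lapply(cfg$sampling, function(s)
    data.frame(time = s$time, window = s$window %||% NA_character_,
               take = s$take %||% "post", stringsAsFactors = FALSE)))
  mps_protocol(events, sampling, duration = cfg$duration,
               label = cfg$label %||% "",
               initial_glucose = cfg$initial_glucose %||% 5.5)
}

#' @rdname read_protocol
#' @param protocol an [mps_protocol()] object.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "mps_protocol"))
  cfg <- list(
    label = protocol$label, duration = protocol$duration,
    initial_glucose = protocol$initial_glucose,
    events = lapply(seq_len(nrow(protocol$events)), function(i)
      as.list(protocol$events[i, ])),
    sampling = lapply(seq_len(nrow(protocol$sampling)), function(i)
      as.list(protocol$sampling[i, ])))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read or write a parameter ensemble as a tabular + metadata bundle
#'
#' The acceptable set (parameter matrix and costs) goes to `<path>.csv`;
#' the search metadata, threshold, bounds and base parameters go to
#' `<path>.yaml`.
#'
#' @param path path prefix (without extension).
#' @return `read_ensemble()` returns an `mps_ensemble`;
#'   `write_ensemble()` invisibly returns `path`.
#' @export
read_ensemble <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  tab <- read.csv(paste0(path, ".csv"))
  free <- do.call(rbind, lapply(meta$free, as.data.frame))
  base <- mps_parameters(
    geometry = do.call(mps_geometry, meta$base$geometry),
    fast = meta$base$fast, slow = meta$base$slow,
    h2 = meta$base$h2, offsets = meta$base$offsets,
    hypothesis = meta$base$hypothesis)
  par <- as.matrix(tab[, free$name, drop = FALSE])
  colnames(par) <- free$name
  flagged <- isTRUE(meta$flagged)
  structure(list(par = par, cost = tab$cost,
                 best = if (flagged) NA_integer_ else which.min(tab$cost),
                 threshold = meta$threshold, df = meta$df,
                 alpha = meta$alpha, free = free, base = base,
                 seed = meta$seed, n_eval = meta$n_eval,
                 flagged = flagged,
                 best_par = unlist(meta$best_par),
                 best_cost = meta$best_cost),
            class = "mps_ensemble")
}

#' @rdname read_ensemble
#' @param ensemble an `mps_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "mps_ensemble"))
  tab <- as.data.frame(ensemble$par)
  tab$cost <- ensemble$cost
  write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
  b <- ensemble$base
  meta <- list(threshold = ensemble$threshold, df = ensemble$df,
               alpha = ensemble$alpha, seed = ensemble$seed,
               n_eval = ensemble$n_eval, flagged = ensemble$flagged,
               best_par = as.list(ensemble$best_par),
               best_cost = ensemble$best_cost,
               free = lapply(seq_len(nrow(ensemble$free)), function(i)
                 as.list(ensemble$free[i, ])),
               base = list(hypothesis = b$hypothesis,
                           geometry = unclass(b$geometry),
                           fast = b$fast, slow = b$slow, h2 = b$h2,
                           offsets = b$offsets))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}
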