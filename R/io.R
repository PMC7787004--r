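# Experiment configuration files: YAML key-value, one experiment kind per
# file, defaults pre-filled from the standard model conditions. Durations may
# be given in seconds with an `_s` suffix (duration_s, settle_s, t_hmax_s);
# they are normalized to ms at load.

.experiment_kinds <- c("two-cell-gap", "two-cell-chemical", "population",
                       "sweep-gw", "sweep-gnap", "carbenoxolone")

.config_defaults <- function(kind) {
  pop <- list(n = 100, n_nap = 40, e_l1_mean = -74, e_l1_sd = 14.8,
              e_l2_mean = -70, e_l2_sd = 14, g_l_mean = 1, g_l_sd = 0.2,
              g_nap_mean = 4, g_nap_sd = 0.8, t_hmax = 9000,
              p_gap = 0.3, p_syn = 0.1, g_gap = 0, w_syn = 0,
              settle = 20000, duration = 60000, dt = 0.05, seed = 1)
  switch(kind,
    "two-cell-gap" = list(e_l1 = -69, e_l2 = -65.5, has_nap1 = TRUE,
                          has_nap2 = TRUE, g_nap = 4, t_hmax = 9000,
                          g_gap = 0.1, settle = 20000, analysis = 100000,
                          dt = 0.05, seed = 1),
    "two-cell-chemical" = list(e_l1 = -65.5, e_l2 = -71.4, has_nap1 = TRUE,
                               has_nap2 = TRUE, g_nap = 4, t_hmax = 9000,
                               w_syn = 1, settle = 20000, analysis = 100000,
                               dt = 0.05, seed = 1),
    "population" = pop,
    "sweep-gw" = c(pop, list(g_grid = c(0, 3, 6), w_grid = c(0, 7.5, 15))),
    "sweep-gnap" = c(pop[setdiff(names(pop), "g_gap")],
                     list(g_gap = 0.06, gnap_grid = seq(2, 5, by = 0.5),
                          n_nap_set = c(20, 30, 40))),
    "carbenoxolone" = c(pop, list(reduction = 0.5, n_runs = 5)),
    stop("unknown experiment kind '", kind, "'"))
}

#' Load an experiment configuration
#'
#' Reads a YAML experiment description, applies the standard defaults of the
#' named experiment kind, normalizes second-suffixed durations
#' (`duration_s`, `settle_s`, `analysis_s`, `t_hmax_s`) to ms and validates
#' ranges. Unknown keys are rejected by name.
#'
#' @param path Path to a YAML file with at least a `kind` entry (one of
#'   `"two-cell-gap"`, `"two-cell-chemical"`, `"population"`, `"sweep-gw"`,
#'   `"sweep-gnap"`, `"carbenoxolone"`).
#' @return A list of class `experiment_config` with every parameter
#'   resolved.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$kind) || !raw$kind %in% .experiment_kinds)
    stop("config must name a 'kind' among: ",
         paste(.experiment_kinds, collapse = ", "))
  kind <- raw$kind
  raw$kind <- NULL
  defaults <- .config_defaults(kind)
  sec_keys <- c(duration_s = "duration", settle_s = "settle",
                analysis_s = "analysis", t_hmax_s = "t_hmax")
  for (sk in names(sec_keys)) {
    if (!is.null(raw[[sk]])) {
      raw[[sec_keys[[sk]]]] <- raw[[sk]] * 1000
      raw[[sk]] <- NULL
    }
  }
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  for (pk in intersect(c("p_gap", "p_syn"), names(cfg)))
    if (cfg[[pk]] < 0 || cfg[[pk]] > 1)
      stop("config key '", pk, "' must be a probability in [0, 1], got ",
           cfg[[pk]])
  for (dk in intersect(c("dt", "duration", "settle", "analysis", "t_hmax"),
                       names(cfg)))
    if (cfg[[dk]] <= 0) stop("config key '", dk, "' must be positive")
  cfg$kind <- kind
  structure(cfg, class = "experiment_config")
}

#' Save a resolved experiment configuration
#'
#' Writes an [load_config()] result back to YAML; loading the written file
#' reproduces the configuration (round trip is the identity).
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> kind = %s\n", x$kind))
  keys <- setdiff(names(x), "kind")
  for (k in keys)
    cat(sprintf("  %s: %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

.fmt_full <- function(x) sprintf("%.17g", x)

#' Write run results to a self-describing output directory
#'
#' Serializes an analyzed run to plain ASCII files: `summary.txt` (key/value
#' lines with the coupling strengths and the mean and SD of the bursting
#' period and amplitude, written at full precision so re-parsing reproduces
#' the in-memory statistics exactly), `spikes.tsv` (neuron id, spike time)
#' when spikes are available, and for sweeps a tidy `sweep.tsv` table
#' (G, W, label, frequency, amplitude). A `config.yaml` provenance block is
#' written when a configuration is supplied.
#'
#' @param x A `population_run`, `two_cell_run`, `sweep_result` or
#'   `cbx_compare`.
#' @param dir Output directory (created if missing).
#' @param config Optional `experiment_config` echoed alongside the results.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(lines, file) {
    p <- file.path(dir, file)
    writeLines(lines, p)
    paths <<- c(paths, p)
  }
  if (inherits(x, "population_run")) {
    s <- x$series
    put(c(sprintf("g_gap %s", .fmt_full(x$pop$spec$g_gap)),
          sprintf("w_syn %s", .fmt_full(x$pop$spec$w_syn)),
          sprintf("label %s", x$label),
          sprintf("n_bursts %d", s$n_bursts),
          sprintf("period_mean_s %s", .fmt_full(s$period_mean)),
          sprintf("period_sd_s %s", .fmt_full(s$period_sd)),
          sprintf("amplitude_mean %s", .fmt_full(s$amplitude)),
          sprintf("amplitude_sd %s", .fmt_full(s$amplitude_sd)),
          sprintf("frequency_hz %s", .fmt_full(s$frequency))),
        "summary.txt")
    spk <- data.frame(neuron = rep(seq_along(x$spikes), lengths(x$spikes)),
                      time_ms = unlist(x$spikes))
    p <- file.path(dir, "spikes.tsv")
    utils::write.table(spk, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  } else if (inherits(x, "two_cell_run")) {
    p <- file.path(dir, "summary.tsv")
    utils::write.table(x$summary, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  } else if (inherits(x, "sweep_result") || is.data.frame(x)) {
    p <- file.path(dir, "sweep.tsv")
    utils::write.table(as.data.frame(x), p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  } else if (inherits(x, "cbx_compare")) {
    p <- file.path(dir, "cbx_runs.tsv")
    utils::write.table(x$runs, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  } else stop("don't know how to write results of class ",
              paste(class(x), collapse = "/"))
  if (!is.null(config)) {
    p <- file.path(dir, "config.yaml")
    save_config(config, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Re-read a population-run summary file
#'
#' Parses a `summary.txt` written by [write_results()] back into a named
#' list with numeric values at full precision.
#'
#' @param path Path to the summary file.
#' @return Named list.
#' @export
read_summary <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, " ", fixed = TRUE)
  vals <- lapply(parts, function(p) {
    v <- paste(p[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num) && !v %in% c("NA", "NaN")) v else num
  })
  stats::setNames(vals, vapply(parts, `[[`, character(1), 1))
}

#' Reference two-cell measurements
#'
#' The published two-cell benchmark tables (effects of electrical and of
#' chemical coupling on regime, resting potential and bursting frequency),
#' in long format.
#'
#' @param table Which benchmark: 1 (electrical coupling, strengths `g_gap`
#'   = 0, 0.05, 0.1, 0.2 nS) or 2 (chemical coupling, `w_syn` = 0, 0.5, 1,
#'   2).
#' @return Data frame with columns `table`, `pair`, `role`, `has_nap`,
#'   `e_l`, `regime`, `strength`, `resting_mv`, `frequency_hz`.
#' @export
two_cell_reference <- function(table = c(1, 2)) {
  table <- match.arg(as.character(table[1]), c("1", "2"))
  ref <- utils::read.csv(system.file("extdata", "two_cell_reference.csv",
                                     package = "burstnet"))
  ref[ref$table == as.integer(table), ]
}

#' Recompute a two-cell benchmark table
#'
#' Runs every (pair, coupling strength) configuration of the chosen
#' benchmark table through [run_two_cell()] and compares the model's regime,
#' resting potential and bursting frequency against the published values,
#' with tolerances of +/- 20% on frequencies and +/- 1.5 mV on voltages
#' (frequencies are sensitive to the burst-onset convention and to the
#' assumed two-cell `t_hmax`).
#'
#' @param table 1 (electrical coupling) or 2 (chemical coupling).
#' @param settle,analysis,dt Simulation windows (ms) per cell, passed to
#'   [run_two_cell()].
#' @param freq_tol Relative frequency tolerance.
#' @param volt_tol Absolute voltage tolerance (mV).
#' @param quiet Suppress per-cell progress output?
#' @return Data frame: reference columns plus `model_regime`,
#'   `model_resting_mv`, `model_frequency_hz`, `freq_ok`, `volt_ok`,
#'   `verdict` (`"PASS"`/`"FAIL"`, regime compared only for uncoupled
#'   cells).
#' @export
reproduce_table <- function(table = 1, settle = 20000, analysis = 100000,
                            dt = 0.05, freq_tol = 0.2, volt_tol = 1.5,
                            quiet = FALSE) {
  ref <- two_cell_reference(table)
  coupling <- if (ref$table[1] == 1) "gap" else "chemical"
  out <- list()
  for (pair_id in unique(ref$pair)) {
    block <- ref[ref$pair == pair_id, ]
    in1 <- block[block$role == "In1", ][1, ]
    in2 <- block[block$role == "In2", ][1, ]
    cells <- list(
      neuron_params(e_l = in1$e_l, has_nap = in1$has_nap == 1),
      neuron_params(e_l = in2$e_l, has_nap = in2$has_nap == 1))
    for (strength in sort(unique(block$strength))) {
      run <- run_two_cell(cells[[1]], cells[[2]],
                          coupling = if (strength == 0) "none" else coupling,
                          strength = strength, settle = settle,
                          analysis = analysis, dt = dt)
      if (!quiet)
        message(sprintf("table %s pair %d strength %g done",
                        table, pair_id, strength))
      for (k in 1:2) {
        role <- c("In1", "In2")[k]
        rrow <- block[block$role == role & block$strength == strength, ]
        mrow <- run$summary[k, ]
        freq_ok <- if (is.na(rrow$frequency_hz)) is.na(mrow$frequency_hz)
        else !is.na(mrow$frequency_hz) &&
          abs(mrow$frequency_hz - rrow$frequency_hz) <=
            freq_tol * rrow$frequency_hz
        volt_ok <- !is.na(mrow$resting_mv) &&
          abs(mrow$resting_mv - rrow$resting_mv) <= volt_tol
        regime_map <- c(silent = "S", bursting = "B", tonic = "T")
        regime_ok <- if (strength == 0)
          regime_map[[mrow$regime]] == rrow$regime else NA
        out[[length(out) + 1]] <- cbind(
          rrow,
          data.frame(model_regime = regime_map[[mrow$regime]],
                     model_resting_mv = mrow$resting_mv,
                     model_frequency_hz = mrow$frequency_hz,
                     freq_ok = freq_ok, volt_ok = volt_ok,
                     regime_ok = regime_ok,
                     verdict = ifelse(freq_ok & volt_ok &
                                        (is.na(regime_ok) | regime_ok),
                                      "PASS", "FAIL")))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
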