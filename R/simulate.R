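#' Simulation control parameters
#'
#' @param dt Integration step (ms). Default 0.05 ms, verified by step-halving
#'   convergence on the bursting configurations.
#' @param duration Total simulated time (ms), including settling.
#' @param settle Settling time (ms) discarded before analysis; the analysis
#'   window is `[settle, duration]`.
#' @param record_v Record membrane-potential traces? Spikes are always
#'   recorded.
#' @param record_dt Trace sampling interval (ms) when `record_v = TRUE`.
#' @param seed Optional integer seed (relevant when the caller samples random
#'   structure before integrating).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.05, duration = 120000, settle = 20000,
                       record_v = FALSE, record_dt = 1, seed = NULL) {
  stopifnot(dt > 0, duration > 0, settle >= 0, settle < duration,
            record_dt >= dt)
  structure(list(dt = dt, duration = duration, settle = settle,
                 record_v = record_v, record_dt = record_dt, seed = seed),
            class = "sim_config")
}

# Normalize parameter input (list of neuron_params or a data frame) to the
# column list consumed by the compiled core.
.params_columns <- function(params, n) {
  if (is.list(params) && !is.data.frame(params) &&
      all(vapply(params, inherits, logical(1), "neuron_params"))) {
    params <- do.call(rbind, lapply(params, function(p)
      data.frame(has_nap = p$has_nap, e_l = p$e_l, g_l = p$g_l,
                 g_nap = p$g_nap, t_hmax = p$t_hmax, g_na = p$g_na,
                 g_k = p$g_k, c = p$c, e_na = p$e_na, e_k = p$e_k)))
  }
  stopifnot(is.data.frame(params), nrow(params) == n,
            all(c("has_nap", "e_l") %in% names(params)))
  defaults <- list(g_l = 1, g_nap = 0, t_hmax = 9000, g_na = 80, g_k = 100,
                   c = 40, e_na = 55, e_k = -80)
  for (nm in names(defaults))
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  list(c = as.numeric(params$c), g_na = as.numeric(params$g_na),
       g_k = as.numeric(params$g_k), g_l = as.numeric(params$g_l),
       g_nap = as.numeric(ifelse(params$has_nap, params$g_nap, 0)),
       e_na = as.numeric(params$e_na), e_k = as.numeric(params$e_k),
       e_l = as.numeric(params$e_l), t_hmax = as.numeric(params$t_hmax),
       has_nap = as.integer(params$has_nap))
}

.edge_list_gap <- function(gap, n) {
  if (is.null(gap)) return(list(a = integer(0), b = integer(0), w = numeric(0)))
  if (!inherits(gap, "gap_matrix")) gap <- gap_matrix(gap)
  stopifnot(nrow(gap) == n)
  idx <- which(upper.tri(gap) & gap > 0, arr.ind = TRUE)
  list(a = idx[, 1] - 1L, b = idx[, 2] - 1L, w = gap[idx])
}

.edge_list_syn <- function(syn, n) {
  if (is.null(syn)) return(list(i = integer(0), j = integer(0), w = numeric(0)))
  if (!inherits(syn, "syn_matrix")) syn <- syn_matrix(syn)
  stopifnot(nrow(syn) == n)
  idx <- which(syn > 0, arr.ind = TRUE)
  list(i = idx[, 1] - 1L, j = idx[, 2] - 1L, w = syn[idx])
}

#' Integrate a coupled neuron network
#'
#' Advances the full network state with a fixed-step second-order Runge-Kutta
#' (midpoint) scheme in the compiled core, recording spike times at upward
#' crossings of -20 mV with a 2 ms refractory guard, and optionally the
#' membrane-potential traces. Gating variables are clamped to \[0, 1\] after
#' each step to absorb floating-point overshoot. Integration aborts with a
#' diagnostic naming the neuron and time if the state becomes non-finite.
#'
#' @param params Neuron parameters: a list of [neuron_params()] objects or a
#'   data frame with columns `has_nap`, `e_l` and optionally `g_l`, `g_nap`,
#'   `t_hmax`, `g_na`, `g_k`, `c`, `e_na`, `e_k` (standard defaults applied).
#' @param state0 Initial state: an n x 5 matrix (columns v, h_na, h_nap,
#'   m_k, s), a list of [neuron_state()] objects, or `NULL` to start every
#'   neuron at steady state for its own `e_l`.
#' @param gap Optional [gap_matrix()] of electrical coupling (nS).
#' @param syn Optional [syn_matrix()] of chemical weights.
#' @param config A [sim_config()].
#' @return An object of class `trajectory`: list with `spikes` (list of
#'   per-neuron spike-time vectors, ms), `time`/`v` (trace grid and n_time x
#'   n matrix, when recorded), `final_state`, and the configuration fields.
#' @export
simulate_network <- function(params, state0 = NULL, gap = NULL, syn = NULL,
                             config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pc <- NULL
  if (is.data.frame(params)) {
    n <- nrow(params)
  } else {
    n <- length(params)
  }
  pc <- .params_columns(params, n)
  if (is.null(state0)) {
    v0 <- pc$e_l
    state0 <- cbind(v = v0, h_na = gate_inf("h_na", v0),
                    h_nap = gate_inf("h_nap", v0),
                    m_k = gate_inf("m_k", v0), s = 0)
  } else if (is.list(state0) && !is.matrix(state0)) {
    state0 <- do.call(rbind, lapply(state0, unclass))
  }
  stopifnot(is.matrix(state0), nrow(state0) == n, ncol(state0) == 5)
  ge <- .edge_list_gap(gap, n)
  se <- .edge_list_syn(syn, n)
  res <- .integrate_cpp(pc, state0,
                        ge$a, ge$b, ge$w, se$i, se$j, se$w,
                        .syn_const$g_syn, .syn_const$e_syn,
                        .syn_const$alpha_s, .syn_const$tau_s,
                        config$dt, config$duration,
                        -20, 2, config$record_v, config$record_dt)
  structure(list(spikes = res$spikes, time = res$time, v = res$v,
                 final_state = res$final_state, n = n,
                 dt = config$dt, duration = config$duration,
                 settle = config$settle),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d neuron(s), %g ms (dt = %g ms, settle %g ms)\n",
              x$n, x$duration, x$dt, x$settle))
  cat(sprintf("  spikes per neuron: %s\n",
              paste(utils::head(lengths(x$spikes), 10), collapse = ", ")))
  if (!is.null(x$v)) cat(sprintf("  traces: %d samples\n", length(x$time)))
  invisible(x)
}

#' Detect spikes in a sampled voltage trace
#'
#' Marks a spike at each upward crossing of the threshold, suppressing
#' re-triggers within the refractory window. This is the same rule the
#' compiled integrator applies at full step resolution.
#'
#' @param v Sampled membrane potential (mV).
#' @param time Sample times (ms), strictly increasing, same length as `v`.
#' @param threshold Spike threshold (mV), default -20.
#' @param refractory Minimum inter-spike interval (ms), default 2.
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(v, time, threshold = -20, refractory = 2) {
  stopifnot(length(v) == length(time), !is.unsorted(time, strictly = TRUE))
  idx <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  out <- numeric(0)
  last <- -Inf
  for (i in idx) {
    if (time[i] - last >= refractory) {
      out <- c(out, time[i])
      last <- time[i]
    }
  }
  out
}

#' Run and analyze a two-cell experiment
#'
#' Simulates a pair of neurons coupled either bidirectionally by a gap
#' junction, unidirectionally by an excitatory chemical synapse, or not at
#' all, then summarizes each neuron's activity over the post-settling
#' analysis window: operating regime (silent / bursting / tonic), bursting
#' frequency, resting potential, plus the source-to-target burst-count ratio.
#'
#' @param cell1,cell2 [neuron_params()] for the two neurons. For chemical
#'   coupling the synapse runs from `cell1` (source) to `cell2` (target)
#'   unless `direction = c(2, 1)`.
#' @param coupling `"none"`, `"gap"` or `"chemical"`.
#' @param strength Gap conductance `g_gap` (nS) or synaptic weight `w_syn`.
#' @param direction Length-2 integer, source then target, for chemical
#'   coupling.
#' @param settle Settling time (ms) discarded before analysis.
#' @param analysis Analysis-window length (ms) after settling.
#' @param dt Integration step (ms).
#' @return A list of class `two_cell_run`: `summary` data frame (one row per
#'   neuron: regime, frequency_hz, resting_mv, n_bursts, n_spikes), `bursts`
#'   (per-neuron [spike_bursts()] series), `ratio` (burst-count ratio of
#'   neuron 1 to neuron 2), and the trajectory.
#' @examples
#' \donttest{
#' pair <- run_two_cell(neuron_params(e_l = -69), neuron_params(e_l = -65.5),
#'                      coupling = "gap", strength = 0.2)
#' pair$summary
#' }
#' @export
run_two_cell <- function(cell1, cell2, coupling = c("none", "gap", "chemical"),
                         strength = 0, direction = c(1, 2),
                         settle = 20000, analysis = 100000, dt = 0.05) {
  coupling <- match.arg(coupling)
  stopifnot(inherits(cell1, "neuron_params"), inherits(cell2, "neuron_params"),
            strength >= 0)
  gap <- syn <- NULL
  if (coupling == "gap" && strength > 0)
    gap <- gap_matrix(matrix(c(0, strength, strength, 0), 2, 2))
  if (coupling == "chemical" && strength > 0) {
    m <- matrix(0, 2, 2)
    m[direction[1], direction[2]] <- strength
    syn <- syn_matrix(m)
  }
  config <- sim_config(dt = dt, duration = settle + analysis, settle = settle,
                       record_v = TRUE, record_dt = 1)
  traj <- simulate_network(list(cell1, cell2), gap = gap, syn = syn,
                           config = config)
  keep <- traj$time >= settle
  window <- c(settle, settle + analysis)
  rows <- list()
  bursts <- list()
  for (k in 1:2) {
    spk <- traj$spikes[[k]]
    spk <- spk[spk >= settle]
    regime <- classify_neuron_regime(spk, window)
    bs <- spike_bursts(spk)
    rest <- resting_potential(traj$v[keep, k], traj$time[keep], spk, regime)
    rows[[k]] <- data.frame(
      neuron = k, regime = regime,
      frequency_hz = if (is.na(bs$frequency)) NA_real_ else bs$frequency,
      resting_mv = rest, n_bursts = bs$n_bursts, n_spikes = length(spk))
    bursts[[k]] <- bs
  }
  ratio <- burst_ratio(bursts[[1]]$onsets, bursts[[2]]$onsets)
  structure(list(summary = do.call(rbind, rows), bursts = bursts,
                 ratio = ratio, trajectory = traj, coupling = coupling,
                 strength = strength, window = window),
            class = "two_cell_run")
}

#' @export
print.two_cell_run <- function(x, ...) {
  cat(sprintf("<two_cell_run> coupling = %s (strength %g)\n",
              x$coupling, x$strength))
  print(x$summary, row.names = FALSE)
  if (!is.na(x$ratio$value))
    cat(sprintf("  burst ratio (1:2) = %d:%d\n", x$ratio$m, x$ratio$n))
  invisible(x)
}

#' Run and analyze one population simulation
#'
#' Samples (or reuses) a heterogeneous population, integrates it, and
#' computes the binned populational firing rate, populational burst series
#' and four-class activity label over the post-settling analysis window.
#'
#' @param spec A [population_spec()] (ignored when `pop` is supplied).
#' @param seed Integer seed fixing parameters, connectivity and initial
#'   conditions.
#' @param settle Settling time (ms); default 20 s, within the standard
#'   10-40 s settling range.
#' @param duration Analysis-window length (ms) after settling; default 60 s.
#' @param dt Integration step (ms).
#' @param bin Rate histogram bin (ms); default 100 ms.
#' @param record_v Record voltage traces (memory-heavy for large
#'   populations)?
#' @param pop Optional pre-sampled `population` from [sample_population()],
#'   e.g. to vary coupling strengths on a fixed randomization.
#' @return A list of class `population_run`: `pop`, `spikes` (analysis-window
#'   spike times per neuron), `activity` ([population_rate()] data frame),
#'   `series` ([detect_population_bursts()]), `label`
#'   ([classify_population_state()]), `trajectory`, `window`.
#' @export
run_population <- function(spec = population_spec(), seed = NULL,
                           settle = 20000, duration = 60000, dt = 0.05,
                           bin = 100, record_v = FALSE, pop = NULL) {
  if (is.null(pop)) pop <- sample_population(spec, seed = seed)
  config <- sim_config(dt = dt, duration = settle + duration, settle = settle,
                       record_v = record_v, record_dt = 1)
  traj <- simulate_network(pop$params, pop$state0, gap = pop$gap,
                           syn = pop$syn, config = config)
  window <- c(settle, settle + duration)
  spikes <- lapply(traj$spikes, function(s) s[s >= window[1] & s <= window[2]])
  activity <- population_rate(spikes, n = pop$spec$n, bin = bin,
                              t_start = window[1], t_end = window[2])
  series <- detect_population_bursts(activity)
  label <- classify_population_state(activity, series)
  structure(list(pop = pop, spikes = spikes, activity = activity,
                 series = series, label = label, trajectory = traj,
                 window = window),
            class = "population_run")
}

#' @export
print.population_run <- function(x, ...) {
  cat(sprintf("<population_run> N = %d, window %g-%g s: %s\n",
              x$pop$spec$n, x$window[1] / 1000, x$window[2] / 1000, x$label))
  if (x$series$n_bursts >= 2)
    cat(sprintf("  %d bursts: frequency %.3f Hz, amplitude %.1f spikes/neuron/s\n",
                x$series$n_bursts, x$series$frequency, x$series$amplitude))
  invisible(x)
}
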