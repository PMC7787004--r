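#' Segment a single-neuron spike train into bursts
#'
#' Partitions a sorted spike train into bursts: consecutive spikes belong to
#' the same burst while their interval does not exceed the segmentation gap.
#' By default the gap starts at `max(300 ms, 3 * median ISI)`, which
#' separates the ~10-100 ms intra-burst intervals of these model neurons
#' from the multi-second interburst pauses across the whole 0.05-0.45 Hz
#' burst-rate range, and leaves a regular tonic train as a single "burst".
#' Conditional bursters can emit a brief rebound miniburst (a few spikes)
#' next to each main burst, separated by a sub-second pause that belongs to
#' the same cycle; any burst with at most `merge_frac` (default 25%) of the
#' upper-quartile spikes-per-burst is therefore merged into the
#' neighbouring burst across the shorter gap, so one burst is counted per
#' cycle. The burst
#' onset is the first spike of each burst; the period is the onset-to-onset
#' difference and the frequency its reciprocal (so frequency * mean period =
#' 1 exactly). With fewer than two bursts the frequency is undefined
#' (`NA`), mirroring tabulated "N/A" entries for non-bursting cells.
#'
#' @param spikes Sorted spike times (ms).
#' @param gap_ms Intra-burst maximum inter-spike interval (ms); `NULL` for
#'   the adaptive default.
#' @param merge_frac Bursts with at most this fraction of the
#'   upper-quartile spikes-per-burst are treated as rebound minibursts and
#'   merged; 0 disables merging.
#' @return A list of class `burst_series`: `onsets` (ms), `n_bursts`,
#'   `spikes_per_burst`, `period_mean`/`period_sd` (s), `frequency` (Hz).
#' @examples
#' spike_bursts(c(0, 20, 40, 5000, 5020, 5040, 10000, 10020))$frequency  # 0.2 Hz
#' @export
spike_bursts <- function(spikes, gap_ms = NULL, merge_frac = 0.25) {
  stopifnot(is.numeric(spikes), !is.unsorted(spikes))
  if (length(spikes) == 0)
    return(structure(list(onsets = numeric(0), n_bursts = 0L,
                          spikes_per_burst = numeric(0),
                          period_mean = NA_real_, period_sd = NA_real_,
                          frequency = NA_real_),
                     class = "burst_series"))
  isi <- diff(spikes)
  if (is.null(gap_ms))
    gap_ms <- max(300, if (length(isi)) 3 * median(isi) else 300)
  id <- cumsum(c(1L, as.integer(isi > gap_ms)))  # burst id per spike
  repeat {
    sizes <- tabulate(id)
    if (length(sizes) < 3 || merge_frac <= 0) break
    onset_k <- spikes[!duplicated(id)]
    end_k <- spikes[!duplicated(id, fromLast = TRUE)]
    # reference is the upper quartile: when rebounds accompany every main
    # burst, half the bursts are minibursts and the median already sits on
    # the miniburst size
    minor <- which(sizes <= merge_frac * stats::quantile(sizes, 0.75,
                                                         names = FALSE))
    if (!length(minor)) break
    b <- minor[1]
    gap_prev <- if (b > 1) onset_k[b] - end_k[b - 1] else Inf
    gap_next <- if (b < length(sizes)) onset_k[b + 1] - end_k[b] else Inf
    target <- if (gap_prev <= gap_next) b - 1L else b + 1L
    id[id == b] <- target
    id <- match(id, sort(unique(id)))  # renumber 1..k
  }
  starts <- which(!duplicated(id))
  onsets <- spikes[starts]
  sizes <- tabulate(id)
  periods <- diff(onsets) / 1000
  structure(list(onsets = onsets, n_bursts = length(onsets),
                 spikes_per_burst = sizes,
                 period_mean = if (length(periods)) mean(periods) else NA_real_,
                 period_sd = if (length(periods) > 1) sd(periods) else NA_real_,
                 frequency = if (length(periods)) 1 / mean(periods) else NA_real_),
            class = "burst_series")
}

#' Classify a single neuron's operating regime
#'
#' Labels the activity in the analysis window as `"silent"` (essentially no
#' spikes), `"bursting"` (at least two bursts separated by quiescent gaps)
#' or `"tonic"` (sustained spiking without burst structure).
#'
#' @param spikes Spike times (ms) within the analysis window.
#' @param window Length-2 analysis window (ms); used only to contextualize
#'   sparse trains.
#' @return One of `"silent"`, `"bursting"`, `"tonic"`.
#' @export
classify_neuron_regime <- function(spikes, window = range(spikes, 0)) {
  stopifnot(is.numeric(spikes))
  if (length(spikes) < 3) return("silent")
  bs <- spike_bursts(spikes)
  if (bs$n_bursts >= 2) "bursting" else "tonic"
}

#' Resting membrane potential of a settled trace
#'
#' For a silent neuron, the mean membrane potential over the last 5 s of the
#' trace. For a bursting or tonic neuron the trace never settles, so the
#' reported value is the mean of the local minima between bursts (bursting)
#' or between consecutive spikes (tonic) -- the only settled, spike-free
#' measure available.
#'
#' @param v Sampled membrane potential (mV) over the analysis window.
#' @param time Sample times (ms).
#' @param spikes Spike times (ms) in the same window.
#' @param regime Label from [classify_neuron_regime()].
#' @return Resting potential (mV).
#' @export
resting_potential <- function(v, time, spikes,
                              regime = classify_neuron_regime(spikes)) {
  stopifnot(length(v) == length(time))
  if (regime == "silent")
    return(mean(v[time >= max(time) - 5000]))
  gap_min <- function(t0, t1) {
    sel <- time > t0 & time < t1
    if (any(sel)) min(v[sel]) else NA_real_
  }
  if (regime == "bursting") {
    bs <- spike_bursts(spikes)
    mins <- numeric(0)
    if (bs$n_bursts >= 2) {
      ends <- vapply(seq_len(bs$n_bursts - 1), function(k) {
        in_burst <- spikes[spikes >= bs$onsets[k] & spikes < bs$onsets[k + 1]]
        max(in_burst)
      }, numeric(1))
      mins <- mapply(gap_min, ends + 50, bs$onsets[-1] - 10)
    }
    return(mean(mins, na.rm = TRUE))
  }
  # tonic: minima between consecutive spikes
  if (length(spikes) < 2) return(mean(v[time >= max(time) - 5000]))
  mins <- mapply(gap_min, utils::head(spikes, -1) + 2, spikes[-1])
  mean(mins, na.rm = TRUE)
}

#' Populational firing-rate histogram
#'
#' Bins all spikes of the population and scales counts to spikes per neuron
#' per second: `rate = count / (N * bin_s)` per bin (default 100 ms bins).
#'
#' @param spikes List of per-neuron spike-time vectors (ms).
#' @param n Population size used for normalization.
#' @param bin Bin width (ms).
#' @param t_start,t_end Window covered by the histogram (ms).
#' @return A data frame of class `population_activity` with columns `time`
#'   (bin centers, ms) and `rate` (spikes/neuron/s); attributes `n`, `bin`.
#' @export
population_rate <- function(spikes, n, bin = 100,
                            t_start = 0, t_end = max(unlist(spikes), t_start + bin)) {
  stopifnot(is.list(spikes), n >= 1, bin > 0, t_end > t_start)
  breaks <- seq(t_start, t_end, by = bin)
  if (breaks[length(breaks)] < t_end) breaks <- c(breaks, t_end)
  all_spk <- unlist(spikes)
  all_spk <- all_spk[all_spk >= t_start & all_spk <= t_end]
  counts <- if (length(all_spk))
    graphics::hist(all_spk, breaks = breaks, plot = FALSE)$counts
  else rep(0, length(breaks) - 1)
  widths <- diff(breaks) / 1000
  out <- data.frame(time = (utils::head(breaks, -1) + breaks[-1]) / 2,
                    rate = counts / (n * widths))
  attr(out, "n") <- n
  attr(out, "bin") <- bin
  class(out) <- c("population_activity", "data.frame")
  out
}

.smooth3 <- function(rate) {
  sm <- stats::filter(rate, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- rate[is.na(sm)]
  as.numeric(sm)
}

# Local maxima of the smoothed rate above a floor, thinned to a minimum
# separation (highest first).
.rate_peaks <- function(time, rate, sm, min_sep, floor) {
  if (length(rate) < 3) return(integer(0))
  cand <- which(diff(sign(diff(sm))) < 0) + 1L
  cand <- cand[rate[cand] >= floor]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(rate[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(time[kept] - time[i]) >= min_sep))
      kept <- c(kept, i)
  sort(kept)
}

#' Detect populational bursts at the 30% threshold
#'
#' Two-pass burst detection on the populational rate: provisional burst
#' peaks are located first (local maxima above the mean rate, at least
#' `min_peak_sep` apart, reaching at least half the maximum rate), their
#' mean height defines the average populational burst amplitude, and a
#' burst onset is then the upward crossing of a threshold at
#' `threshold_frac` (default 30%) of that amplitude, located by walking
#' back from each burst peak (so weaker precursor bumps and noise
#' re-crossings on the rising phase of a cycle do not shift or duplicate
#' onsets). A burst peak must reach half the average burst amplitude. The
#' first
#' `n_omit` cycles may additionally be discarded as transitional (the
#' settling period discarded before analysis already plays most of this
#' role). Per-burst amplitude is the maximum rate between consecutive
#' onsets; the series reports mean and SD of period and amplitude and the
#' frequency as the reciprocal mean period.
#'
#' @param activity A [population_rate()] data frame.
#' @param threshold_frac Onset threshold as a fraction of the mean burst
#'   amplitude.
#' @param min_peak_sep Minimum separation of provisional peaks (ms).
#' @param n_omit Number of leading cycles discarded as transitional.
#' @return A list of class `burst_series`: `onsets` (ms), `n_bursts`,
#'   `amplitudes`, `amplitude`/`amplitude_sd` (spikes/neuron/s),
#'   `period_mean`/`period_sd` (s), `frequency` (Hz), `threshold`.
#' @export
detect_population_bursts <- function(activity, threshold_frac = 0.3,
                                     min_peak_sep = 500, n_omit = 2) {
  stopifnot(inherits(activity, "population_activity") ||
              all(c("time", "rate") %in% names(activity)))
  time <- activity$time
  rate <- activity$rate
  empty <- structure(list(onsets = numeric(0), n_bursts = 0L,
                          amplitudes = numeric(0), amplitude = NA_real_,
                          amplitude_sd = NA_real_, period_mean = NA_real_,
                          period_sd = NA_real_, frequency = NA_real_,
                          threshold = NA_real_),
                     class = "burst_series")
  sm <- .smooth3(rate)
  peaks <- .rate_peaks(time, rate, sm, min_peak_sep, 0.5 * max(rate))
  if (!length(peaks)) return(empty)
  peak_amp <- mean(rate[peaks])
  threshold <- threshold_frac * peak_amp
  # burst peaks: maxima reaching half the average burst amplitude; the
  # onset of each burst is the threshold crossing found by walking back
  # from its peak on the lightly smoothed rate (binned counts carry Poisson
  # noise that would otherwise trigger spurious onsets near threshold)
  bpk <- .rate_peaks(time, rate, sm, min_peak_sep, 0.5 * peak_amp)
  up <- integer(0)
  for (p in bpk) {
    below <- which(sm[seq_len(max(p - 1, 1))] < threshold)
    if (!length(below)) next
    i <- max(below) + 1L
    # peaks not separated by a dip below threshold share one burst
    if (!length(up) || i > up[length(up)]) up <- c(up, i)
  }
  burst_max <- function(idx) vapply(seq_along(idx), function(k) {
    hi <- if (k < length(idx)) idx[k + 1] - 1L else length(rate)
    max(rate[idx[k]:hi])
  }, numeric(1))
  # thin onsets separated by much less than the typical cycle (noise
  # re-crossings on a burst's falling phase)
  if (length(up) > 2) {
    repeat {
      iv <- diff(time[up])
      short <- which(iv < 0.33 * median(iv))
      if (!length(short)) break
      up <- up[-(short[1] + 1L)]
      if (length(up) <= 2) break
    }
  }
  if (n_omit > 0 && length(up) > n_omit + 2) up <- up[-seq_len(n_omit)]
  if (length(up) < 2) {
    empty$threshold <- threshold
    empty$onsets <- time[up]
    empty$n_bursts <- length(up)
    return(empty)
  }
  onsets <- time[up]
  amps <- burst_max(up)
  periods <- diff(onsets) / 1000
  structure(list(onsets = onsets, n_bursts = length(onsets),
                 amplitudes = amps, amplitude = mean(amps),
                 amplitude_sd = sd(amps),
                 period_mean = mean(periods),
                 period_sd = if (length(periods) > 1) sd(periods) else NA_real_,
                 frequency = 1 / mean(periods), threshold = threshold),
            class = "burst_series")
}

#' @export
print.burst_series <- function(x, ...) {
  cat(sprintf("<burst_series> %d burst(s)\n", x$n_bursts))
  if (!is.na(x$frequency))
    cat(sprintf("  period %.2f +/- %.2f s; frequency %.3f Hz\n",
                x$period_mean, ifelse(is.na(x$period_sd), 0, x$period_sd),
                x$frequency))
  if (!is.null(x$amplitude) && !is.na(x$amplitude))
    cat(sprintf("  amplitude %.1f +/- %.1f spikes/neuron/s\n",
                x$amplitude, ifelse(is.na(x$amplitude_sd), 0, x$amplitude_sd)))
  invisible(x)
}

#' Four-class populational activity label
#'
#' Assigns each analyzed simulation to exactly one of the four populational
#' regimes: `"none"` (essentially no activity), `"low/unstable"` (mean burst
#' amplitude below 10 spikes/neuron/s, or the SD of the burst period at or
#' above 50% of its mean, or too few bursts to certify stability),
#' `"tonic"` (sustained rate of at least 10 spikes/neuron/s that never
#' crosses back below the burst-onset threshold), or `"stable bursting"`.
#'
#' @param activity A [population_rate()] data frame.
#' @param series The matching [detect_population_bursts()] result.
#' @param amp_min Stability amplitude floor (spikes/neuron/s).
#' @param cv_max Maximal SD/mean of the burst period for stability.
#' @return One of `"none"`, `"low/unstable"`, `"stable bursting"`, `"tonic"`.
#' @export
classify_population_state <- function(activity,
                                      series = detect_population_bursts(activity),
                                      amp_min = 10, cv_max = 0.5) {
  rate <- activity$rate
  if (!length(rate) || max(rate) < 1) return("none")
  threshold <- if (!is.na(series$threshold)) series$threshold else 0.3 * max(rate)
  down <- any(rate[-1] < threshold & rate[-length(rate)] >= threshold)
  tonic <- mean(rate) >= amp_min && !down && min(rate) >= threshold
  if (tonic) return("tonic")
  if (series$n_bursts < 3) return("low/unstable")
  cv <- if (is.na(series$period_sd)) Inf else series$period_sd / series$period_mean
  if (series$amplitude < amp_min || cv >= cv_max) return("low/unstable")
  "stable bursting"
}

#' Burst-count ratio of two burst series
#'
#' Reduced ratio M:N of burst counts over the common window of two onset
#' series (e.g. source and target of a chemical synapse, where weak coupling
#' yields 2:1 entrainment). The empirical count ratio is snapped to the
#' nearest small rational (denominator at most 4) when within 15%; a 1:1
#' ratio additionally requires equal counts. Undefined if either series is
#' empty.
#'
#' @param onsets_a,onsets_b Burst onset times (ms) of the two series.
#' @return A list with `m`, `n` (reduced integer ratio), `value` (= m/n),
#'   and the raw counts `count_a`, `count_b`.
#' @export
burst_ratio <- function(onsets_a, onsets_b) {
  if (!length(onsets_a) || !length(onsets_b))
    return(list(m = NA_integer_, n = NA_integer_, value = NA_real_,
                count_a = length(onsets_a), count_b = length(onsets_b)))
  lo <- max(min(onsets_a), min(onsets_b)) - 1e-6
  hi <- min(max(onsets_a), max(onsets_b)) + 1e-6
  ca <- sum(onsets_a >= lo & onsets_a <= hi)
  cb <- sum(onsets_b >= lo & onsets_b <= hi)
  if (ca == 0 || cb == 0)
    return(list(m = NA_integer_, n = NA_integer_, value = NA_real_,
                count_a = ca, count_b = cb))
  r <- ca / cb
  best <- NULL
  for (den in 1:4) {
    num <- max(1L, round(r * den))
    g <- .gcd(num, den)
    cand <- c(num / g, den / g)
    err <- abs(r - cand[1] / cand[2]) / (cand[1] / cand[2])
    if (is.null(best) || err < best$err)
      best <- list(m = cand[1], n = cand[2], err = err)
  }
  if (best$err <= 0.15 && !(best$m == best$n && ca != cb))
    return(list(m = as.integer(best$m), n = as.integer(best$n),
                value = best$m / best$n, count_a = ca, count_b = cb))
  g <- .gcd(ca, cb)
  list(m = as.integer(ca / g), n = as.integer(cb / g), value = ca / cb,
       count_a = ca, count_b = cb)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Spike-time synchrony index
#'
#' Mean pairwise Pearson correlation of binned spike counts (default 100 ms
#' bins) over a chosen subset of neurons. Pairs in which either neuron has
#' zero count variance are skipped; the index is `NA` if no pair remains.
#'
#' @param spikes List of per-neuron spike-time vectors (ms).
#' @param ids Indices of the neurons entering the index (default all).
#' @param bin Bin width (ms).
#' @param window Length-2 time window (ms).
#' @return Mean pairwise correlation in \[-1, 1\].
#' @export
synchrony_index <- function(spikes, ids = seq_along(spikes), bin = 100,
                            window = range(unlist(spikes))) {
  breaks <- seq(window[1], window[2] + bin, by = bin)
  counts <- vapply(spikes[ids], function(s) {
    s <- s[s >= window[1] & s <= window[2]]
    graphics::hist(s, breaks = breaks, plot = FALSE)$counts
  }, numeric(length(breaks) - 1))
  keep <- apply(counts, 2, sd) > 0
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) < 2) return(NA_real_)
  cm <- stats::cor(counts)
  mean(cm[upper.tri(cm)])
}

#' Two-parameter (G, W) sweep of populational activity
#'
#' Classifies populational activity over a grid of aggregate electrical (G,
#' nS) and chemical (W) coupling. One randomized population (parameters,
#' connectivity pattern, initial conditions) is drawn per sweep and only the
#' per-edge strengths `g_gap = G / (N p_gap)` and `w_syn = W / (N p_syn)`
#' are rescaled between cells, so cells differ only in coupling strength.
#'
#' @param spec A [population_spec()]; its `g_gap`/`w_syn` are overridden.
#' @param g_grid Aggregate electrical couplings G (nS).
#' @param w_grid Aggregate chemical couplings W.
#' @param seed Integer seed for the shared randomization.
#' @param ... Passed to [run_population()] (`settle`, `duration`, `dt`, ...).
#' @return A data frame of class `sweep_result` with one row per (G, W):
#'   `g`, `w`, `label`, `frequency_hz`, `amplitude` (frequency and amplitude
#'   are `NA` unless the cell is stable bursting).
#' @export
sweep_gw <- function(spec = population_spec(), g_grid, w_grid, seed = NULL,
                     ...) {
  stopifnot(inherits(spec, "population_spec"))
  base <- spec
  base$g_gap <- 1
  base$w_syn <- 1
  pop0 <- sample_population(base, seed = seed)
  rows <- list()
  for (g in g_grid) for (w in w_grid) {
    pop <- pop0
    pop$gap <- gap_matrix(unclass(pop0$gap) *
                            per_edge_strength(g, spec$n, max(spec$p_gap, 1e-12)))
    pop$syn <- syn_matrix(unclass(pop0$syn) *
                            per_edge_strength(w, spec$n, max(spec$p_syn, 1e-12)))
    run <- run_population(pop = pop, ...)
    stable <- run$label == "stable bursting"
    rows[[length(rows) + 1]] <- data.frame(
      g = g, w = w, label = run$label,
      frequency_hz = if (stable) run$series$frequency else NA_real_,
      amplitude = if (stable) run$series$amplitude else NA_real_)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Sweep of INaP conductance and INaP-subpopulation size
#'
#' Populational bursting frequency and amplitude as a function of the mean
#' INaP conductance (grid over the 2-5 nS range) for several sizes of the
#' INaP-carrying subpopulation, at fixed electrical coupling (default
#' `g_gap` = 0.06 nS, no chemical synapses). Bursting frequency grows with
#' both the conductance and the subpopulation size; bursting emerges at
#' lower conductances in larger subpopulations.
#'
#' @param spec Base [population_spec()].
#' @param gnap_grid Mean INaP conductances (nS).
#' @param n_nap_set INaP subpopulation sizes.
#' @param g_gap Gap-junction conductance (nS).
#' @param seed Integer seed; each (conductance, size) cell reuses it so cells
#'   differ only in the swept parameters.
#' @param ... Passed to [run_population()].
#' @return Data frame: `g_nap`, `n_nap`, `label`, `frequency_hz`,
#'   `amplitude` (`NA` unless stable bursting).
#' @export
sweep_gnap <- function(spec = population_spec(), gnap_grid = seq(2, 5, by = 0.5),
                       n_nap_set = c(20, 30, 40), g_gap = 0.06, seed = NULL,
                       ...) {
  rows <- list()
  for (n_nap in n_nap_set) for (gnap in gnap_grid) {
    sp <- spec
    sp$n_nap <- n_nap
    sp$g_nap_mean <- gnap
    sp$g_nap_sd <- spec$g_nap_sd / spec$g_nap_mean * gnap  # keep 20% CV
    sp$g_gap <- g_gap
    run <- run_population(sp, seed = seed, ...)
    stable <- run$label == "stable bursting"
    rows[[length(rows) + 1]] <- data.frame(
      g_nap = gnap, n_nap = n_nap, label = run$label,
      frequency_hz = if (stable) run$series$frequency else NA_real_,
      amplitude = if (stable) run$series$amplitude else NA_real_)
  }
  do.call(rbind, rows)
}

#' Gap-junction block comparison (carbenoxolone analogue)
#'
#' Models pharmacological gap-junction block as a fractional reduction
#' (default 50%) of every gap conductance. For each of `n_runs` parameter
#' randomizations the same population is simulated before and after the
#' reduction; burst frequency and amplitude (normalized to baseline) are
#' reported per run together with paired means. Runs whose baseline is not
#' stable bursting are flagged.
#'
#' @param spec A [population_spec()] whose baseline generates stable
#'   bursting (default: standard population with `g_gap` = 0.066 nS).
#' @param reduction Fractional reduction of gap conductances in \[0, 1\].
#' @param n_runs Number of parameter randomizations.
#' @param seed Base seed; run k uses `seed + k - 1`.
#' @param ... Passed to [run_population()].
#' @return A list of class `cbx_compare`: `runs` data frame (seed, baseline
#'   and reduced frequency, baseline-normalized amplitudes, labels, flag)
#'   and `means` (paired means over unflagged runs).
#' @export
carbenoxolone_compare <- function(spec = NULL, reduction = 0.5, n_runs = 5,
                                  seed = 1, ...) {
  if (is.null(spec)) spec <- population_spec(g_gap = 0.066)
  stopifnot(reduction >= 0, reduction <= 1)
  rows <- list()
  for (k in seq_len(n_runs)) {
    s <- seed + k - 1
    pop <- sample_population(spec, seed = s)
    base <- run_population(pop = pop, ...)
    pop_red <- pop
    pop_red$gap <- gap_matrix(unclass(pop$gap) * (1 - reduction))
    red <- run_population(pop = pop_red, ...)
    rows[[k]] <- data.frame(
      seed = s,
      freq_base = base$series$frequency, freq_reduced = red$series$frequency,
      amp_base_norm = 1,
      amp_reduced_norm = red$series$amplitude / base$series$amplitude,
      label_base = base$label, label_reduced = red$label,
      flagged = base$label != "stable bursting")
  }
  runs <- do.call(rbind, rows)
  ok <- !runs$flagged
  means <- data.frame(
    freq_base = mean(runs$freq_base[ok]),
    freq_reduced = mean(runs$freq_reduced[ok], na.rm = TRUE),
    amp_base_norm = 1,
    amp_reduced_norm = mean(runs$amp_reduced_norm[ok], na.rm = TRUE))
  structure(list(runs = runs, means = means, reduction = reduction),
            class = "cbx_compare")
}

#' @export
print.cbx_compare <- function(x, ...) {
  cat(sprintf("<cbx_compare> %d%% gap-conductance reduction, %d runs\n",
              round(100 * x$reduction), nrow(x$runs)))
  print(x$runs, row.names = FALSE)
  cat("means:\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}
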