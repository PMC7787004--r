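# Independent oracles used across the suite. These transcribe the model
# equations directly (no package code) so that the implementation and its
# check never share a code path.

# Exact channel-kinetics formulas, transcribed independently of R/gates.R.
oracle_kinetics <- function(v, t_hmax = 9000) {
  list(
    m_na_inf  = (1 + exp(-(v + 42.5) / 6.5))^-1,
    h_na_inf  = (1 + exp((v + 65.5) / 10.2))^-1,
    tau_h_na  = 35.2 / cosh((v + 65.5) / 12.8),
    m_nap_inf = (1 + exp(-(v + 52) / 3.2))^-1,
    h_nap_inf = (1 + exp((v + 57) / 5))^-1,
    tau_h_nap = t_hmax / cosh((v + 57) / 8),
    m_k_inf   = (1 + exp(-(v + 34.5) / 5))^-1,
    tau_m_k   = 10 / cosh((v + 34.5) / 10),
    s_inf     = (1 + exp(-(v + 20) / 2))^-1
  )
}

# Right-hand side of the full coupled system with exact formulas, for
# deSolve. y is the stacked per-neuron state (v, h_na, h_nap, m_k, s);
# p holds e_l, g_nap (0 for neurons without INaP), t_hmax, g_l and the
# coupling matrices gap (symmetric) and syn (directed, w[i,j] = i -> j).
oracle_rhs <- function(t, y, p) {
  n <- length(p$e_l)
  d <- numeric(5 * n)
  v_all <- y[5 * (seq_len(n) - 1) + 1]
  s_all <- y[5 * (seq_len(n) - 1) + 5]
  for (k in seq_len(n)) {
    o <- 5 * (k - 1)
    v <- y[o + 1]; h_na <- y[o + 2]; h_nap <- y[o + 3]
    m_k <- y[o + 4]; s <- y[o + 5]
    kin <- oracle_kinetics(v, p$t_hmax[k])
    i_na <- 80 * kin$m_na_inf^3 * h_na * (v - 55)
    i_nap <- p$g_nap[k] * kin$m_nap_inf * h_nap * (v - 55)
    i_k <- 100 * m_k^4 * (v + 80)
    i_l <- p$g_l[k] * (v - p$e_l[k])
    i_syn <- if (is.null(p$syn)) 0 else sum(p$syn[, k] * s_all) * (v - 0)
    gap_drive <- if (is.null(p$gap)) 0 else sum(p$gap[, k] * (v_all - v))
    d[o + 1] <- (-(i_na + i_nap + i_k + i_l + i_syn) + gap_drive) / 40
    d[o + 2] <- (kin$h_na_inf - h_na) / kin$tau_h_na
    d[o + 3] <- (kin$h_nap_inf - h_nap) / kin$tau_h_nap
    d[o + 4] <- (kin$m_k_inf - m_k) / kin$tau_m_k
    d[o + 5] <- kin$s_inf * (1 - s) - s / 15
  }
  list(d)
}

oracle_state0 <- function(e_l) {
  unlist(lapply(e_l, function(v) {
    kin <- oracle_kinetics(v)
    c(v, kin$h_na_inf, kin$h_nap_inf, kin$m_k_inf, 0)
  }))
}

# High-accuracy adaptive-step integration of the same system (lsoda).
oracle_integrate <- function(e_l, g_nap, times, gap = NULL, syn = NULL,
                             g_l = rep(1, length(e_l)),
                             t_hmax = rep(9000, length(e_l))) {
  deSolve::lsoda(oracle_state0(e_l), times, oracle_rhs,
                 list(e_l = e_l, g_nap = g_nap, g_l = g_l, t_hmax = t_hmax,
                      gap = gap, syn = syn),
                 rtol = 1e-9, atol = 1e-9, maxsteps = 1e7)
}

# Hysteresis-based spike counter: a spike is an excursion that rises above
# the upper threshold after having been below the lower one.
oracle_spike_count <- function(v, upper = -20, lower = -40) {
  armed <- v[1] < lower
  count <- 0L
  for (x in v[-1]) {
    if (armed && x >= upper) {
      count <- count + 1L
      armed <- FALSE
    } else if (!armed && x < lower) {
      armed <- TRUE
    }
  }
  count
}

# Synthetic populational-rate generator with known burst onsets:
# sharp-rising bursts with a half-cosine decay on a low baseline, optional
# additive noise. Returns the activity frame plus the ground truth.
make_burst_fixture <- function(n_bursts = 8, period_s = 3, burst_dur_s = 1,
                               amplitude = 25, baseline = 0.5,
                               noise_sd = 0, bin = 100, jitter_s = 0) {
  t_end <- (n_bursts + 1) * period_s * 1000
  time <- seq(bin / 2, t_end - bin / 2, by = bin)
  onsets <- (seq_len(n_bursts) - 0.5) * period_s * 1000 +
    if (jitter_s > 0) runif(n_bursts, -jitter_s, jitter_s) * 1000 else 0
  onsets <- round(onsets / bin) * bin  # align the sharp edge to the binning
  rate <- rep(baseline, length(time))
  for (on in onsets) {
    sel <- time >= on & time <= on + burst_dur_s * 1000
    rate[sel] <- rate[sel] +
      amplitude * cos(0.5 * pi * (time[sel] - on) / (burst_dur_s * 1000))
  }
  if (noise_sd > 0) rate <- pmax(0, rate + rnorm(length(rate), 0, noise_sd))
  activity <- data.frame(time = time, rate = rate)
  attr(activity, "n") <- 100
  attr(activity, "bin") <- bin
  class(activity) <- c("population_activity", "data.frame")
  list(activity = activity, onsets = onsets, amplitude = amplitude + baseline)
}

# Standard two-cell cells used across tests
cell_nap <- function(e_l) neuron_params(e_l = e_l, has_nap = TRUE)
cell_simple <- function(e_l) neuron_params(e_l = e_l, has_nap = FALSE)
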