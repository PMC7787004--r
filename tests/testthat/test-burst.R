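test_that("burst segmentation recovers onsets, periods and reciprocity", {
  # three bursts of three spikes starting at 0, 5, 10 s
  spk <- c(0, 20, 40, 5000, 5020, 5040, 10000, 10020, 10040)
  bs <- spike_bursts(spk)
  expect_equal(bs$onsets, c(0, 5000, 10000))
  expect_equal(bs$period_mean, 5)
  expect_equal(bs$frequency, 0.2)
  expect_equal(bs$frequency * bs$period_mean, 1)
  # a perfectly regular tonic train is one burst, frequency undefined
  tonic <- spike_bursts(seq(0, 60000, by = 50))
  expect_equal(tonic$n_bursts, 1L)
  expect_true(is.na(tonic$frequency))
  # empty train
  expect_equal(spike_bursts(numeric(0))$n_bursts, 0L)
})

test_that("jittered synthetic trains give back the generating onsets", {
  set.seed(42)
  for (rep in 1:10) {
    n_b <- 7
    period <- runif(1, 2500, 8000)
    onsets <- (0:(n_b - 1)) * period + rnorm(n_b, 0, period / 40)
    spk <- sort(unlist(lapply(onsets, function(on)
      on + cumsum(c(0, runif(sample(5:20, 1), 10, 80))))))
    bs <- spike_bursts(spk)
    expect_equal(bs$n_bursts, n_b)
    expect_equal(bs$onsets, sort(onsets), tolerance = 1e-6)
  }
})

test_that("rebound minibursts are merged into their cycle", {
  # main bursts every 5 s, 2-spike rebound 800 ms after each burst end
  mains <- seq(0, 25000, by = 5000)
  spk <- sort(c(unlist(lapply(mains, function(on) on + seq(0, 400, by = 20))),
                unlist(lapply(mains, function(on) on + 1200 + c(0, 20)))))
  bs <- spike_bursts(spk)
  expect_equal(bs$n_bursts, length(mains))
  expect_equal(bs$period_mean, 5)
})

test_that("single-neuron regime labels partition the observed behaviors", {
  expect_equal(classify_neuron_regime(numeric(0)), "silent")
  expect_equal(classify_neuron_regime(c(1000, 8000)), "silent")
  expect_equal(classify_neuron_regime(seq(0, 60000, by = 50)), "tonic")
  spk <- c(0, 20, 40, 5000, 5020, 5040, 10000, 10020)
  expect_equal(classify_neuron_regime(spk), "bursting")
})

test_that("resting potential reduces to the leak equilibrium for a passive cell", {
  p <- data.frame(has_nap = FALSE, e_l = -70, g_l = 1, g_na = 0, g_k = 0)
  tr <- simulate_network(p, config = sim_config(duration = 10000, settle = 0,
                                                record_v = TRUE))
  expect_equal(resting_potential(tr$v[, 1], tr$time, numeric(0), "silent"),
               -70, tolerance = 1e-6)
})

test_that("population rate normalizes counts per neuron per second", {
  spikes <- list(c(150, 151, 152), c(160), numeric(0))
  act <- population_rate(spikes, n = 100, bin = 100, t_start = 0, t_end = 1000)
  expect_equal(nrow(act), 10)
  expect_equal(act$rate[2], 4 / (100 * 0.1))  # 4 spikes in bin 2
  expect_equal(sum(act$rate > 0), 1)
  expect_true(all(population_rate(list(numeric(0)), n = 5, bin = 100,
                                  t_start = 0, t_end = 500)$rate == 0))
  # Poisson trains: mean rate within 3 SE of the generating 5 Hz
  set.seed(9)
  n <- 50; dur_s <- 60
  trains <- replicate(n, sort(runif(rpois(1, 5 * dur_s), 0, dur_s * 1000)),
                      simplify = FALSE)
  act <- population_rate(trains, n = n, bin = 100, t_start = 0,
                         t_end = dur_s * 1000)
  se <- sqrt(5 / (n * dur_s))
  expect_lt(abs(mean(act$rate) - 5), 3 * se)
})

test_that("population burst detector handles square, constant and noisy rates", {
  # square wave 0/20 with 2 s period: onsets at rising edges, 0.5 Hz, amp 20
  time <- seq(50, 40000, by = 100)
  rate <- ifelse(time %% 2000 < 1000, 20, 0)
  act <- structure(data.frame(time = time, rate = rate),
                   class = c("population_activity", "data.frame"))
  bs <- detect_population_bursts(act, n_omit = 0)
  expect_equal(bs$frequency, 0.5, tolerance = 0.01)
  expect_equal(bs$amplitude, 20)
  expect_equal(bs$threshold, 6)
  expect_true(all(diff(bs$onsets) == 2000))
  # constant rate: no upward crossings, no bursts
  act$rate <- rep(15, length(time))
  expect_equal(detect_population_bursts(act)$n_bursts, 0L)
  # noisy generator fixtures: onset recovery within one bin
  set.seed(5)
  for (i in 1:50) {
    amp <- runif(1, 15, 40)
    fix <- make_burst_fixture(n_bursts = sample(6:12, 1),
                              period_s = runif(1, 2.5, 6),
                              amplitude = amp,
                              noise_sd = 0.1 * amp, jitter_s = 0.2)
    bs <- detect_population_bursts(fix$activity, n_omit = 0)
    expect_equal(bs$n_bursts, length(fix$onsets))
    expect_lt(max(abs(bs$onsets - fix$onsets)), 1.5 * attr(fix$activity, "bin"))
  }
})

test_that("population labels are exhaustive, exclusive and follow the taxonomy", {
  time <- seq(50, 60000, by = 100)
  lab <- function(rate) {
    act <- structure(data.frame(time = time, rate = rate),
                     class = c("population_activity", "data.frame"))
    classify_population_state(act)
  }
  expect_equal(lab(rep(0, length(time))), "none")
  expect_equal(lab(rep(15, length(time))), "tonic")
  # clean bursts of amplitude 8: below the 10 spikes/neuron/s floor
  low <- ifelse(time %% 4000 < 1500, 8, 0.2)
  expect_equal(lab(low), "low/unstable")
  # strong regular bursts: stable
  good <- ifelse(time %% 4000 < 1500, 25, 0.2)
  expect_equal(lab(good), "stable bursting")
  # irregular periods: SD/mean above 50%
  set.seed(3)
  onsets <- cumsum(runif(18, 800, 6500))
  rate <- rep(0.2, length(time))
  for (on in onsets) rate[time >= on & time <= on + 700] <- 25
  res <- lab(rate)
  expect_true(res %in% c("low/unstable", "stable bursting"))
  act <- structure(data.frame(time = time, rate = rate),
                   class = c("population_activity", "data.frame"))
  s <- detect_population_bursts(act)
  if (!is.na(s$period_sd) && s$period_sd / s$period_mean >= 0.5)
    expect_equal(res, "low/unstable")
  # every label comes from the closed four-class set
  for (r in list(rep(0, length(time)), rep(3, length(time)), low, good))
    expect_true(lab(r) %in% c("none", "low/unstable", "stable bursting",
                              "tonic"))
})

test_that("burst ratios reduce correctly and snap to small rationals", {
  a <- seq(0, 45000, by = 5000)    # 10 bursts
  b <- seq(0, 45000, by = 5000)
  expect_equal(burst_ratio(a, b)$value, 1)
  expect_equal(burst_ratio(a, b)$m, 1L)
  # strict 2:1 interleaving
  fast <- seq(0, 40000, by = 2500)
  slow <- seq(0, 40000, by = 5000)
  r <- burst_ratio(fast, slow)
  expect_equal(c(r$m, r$n), c(2L, 1L))
  # constructed 3:2
  r32 <- burst_ratio(seq(0, 60000, by = 2000), seq(0, 60000, by = 3000))
  expect_equal(c(r32$m, r32$n), c(3L, 2L))
  expect_true(is.na(burst_ratio(numeric(0), a)$value))
})

test_that("synchrony index rises from independent to locked trains", {
  set.seed(11)
  indep <- replicate(10, sort(runif(300, 0, 60000)), simplify = FALSE)
  locked <- replicate(10, {
    base <- seq(0, 59000, by = 3000)
    sort(unlist(lapply(base, function(on) on + runif(15, 0, 600))))
  }, simplify = FALSE)
  si_i <- synchrony_index(indep, window = c(0, 60000))
  si_l <- synchrony_index(locked, window = c(0, 60000))
  expect_lt(si_i, 0.2)
  expect_gt(si_l, 0.6)
  expect_gt(si_l, si_i)
})
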