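test_that("passive membrane follows the closed-form RC relaxation", {
  # all active conductances zero: V(t) = E_L + (V0 - E_L) exp(-t / (C/g_L)),
  # time constant 40 ms
  p <- data.frame(has_nap = FALSE, e_l = -70, g_l = 1, g_na = 0, g_k = 0)
  st <- cbind(v = -50, h_na = 0.5, h_nap = 0.5, m_k = 0, s = 0)
  tr <- simulate_network(p, st, config = sim_config(dt = 0.05, duration = 200,
                                                    settle = 0,
                                                    record_v = TRUE,
                                                    record_dt = 1))
  expected <- -70 + 20 * exp(-tr$time / 40)
  expect_lt(max(abs(tr$v[, 1] - expected) / abs(expected)), 0.005)
})

test_that("single-neuron integration tracks the adaptive-step oracle", {
  times <- seq(0, 3000, by = 1)
  o <- oracle_integrate(e_l = -65.5, g_nap = 4, times = times)
  tr <- simulate_network(data.frame(has_nap = TRUE, e_l = -65.5, g_nap = 4),
                         config = sim_config(dt = 0.05, duration = 3000,
                                             settle = 0, record_v = TRUE,
                                             record_dt = 1))
  spk_o <- detect_spikes(o[, 2], times)
  spk_m <- detect_spikes(tr$v[, 1], tr$time)
  # subthreshold approach to the first spike agrees pointwise
  pre <- seq_len(max(10, floor(min(spk_o[1], spk_m[1])) - 10))
  expect_lt(max(abs(tr$v[pre, 1] - o[pre, 2])), 0.1)
  # burst onset and overall spiking agree; small phase drift accumulates
  # over the segment, so counts are compared with slack
  expect_lt(abs(spk_m[1] - spk_o[1]), 5)
  expect_lt(abs(length(spk_m) - length(spk_o)) / length(spk_o), 0.1)
})

test_that("integration is deterministic and coupling-free networks decouple", {
  cells <- list(cell_nap(-69), cell_nap(-65.5))
  cfg <- sim_config(duration = 30000, settle = 0)
  t1 <- simulate_network(cells, config = cfg)
  t2 <- simulate_network(cells, config = cfg)
  expect_identical(t1$spikes, t2$spikes)
  # each uncoupled neuron matches its isolated simulation exactly
  solo1 <- simulate_network(cells[1], config = cfg)
  solo2 <- simulate_network(cells[2], config = cfg)
  expect_identical(t1$spikes[[1]], solo1$spikes[[1]])
  expect_identical(t1$spikes[[2]], solo2$spikes[[1]])
})

test_that("identical symmetrically coupled neurons stay identical", {
  cells <- list(cell_nap(-67), cell_nap(-67))
  gap <- gap_matrix(matrix(c(0, 0.1, 0.1, 0), 2, 2))
  tr <- simulate_network(cells, gap = gap,
                         config = sim_config(duration = 30000, settle = 0,
                                             record_v = TRUE))
  expect_equal(tr$v[, 1], tr$v[, 2])
  expect_identical(tr$spikes[[1]], tr$spikes[[2]])
})

test_that("step halving changes the intrinsic burst frequency by under 1%", {
  freq <- vapply(c(0.05, 0.025), function(dt) {
    tr <- simulate_network(list(cell_nap(-69)),
                           config = sim_config(dt = dt, duration = 80000,
                                               settle = 20000))
    spk <- tr$spikes[[1]]
    spike_bursts(spk[spk >= 20000])$frequency
  }, numeric(1))
  expect_lt(abs(freq[1] - freq[2]) / freq[2], 0.01)
})

test_that("spike detection matches a hysteresis oracle on clean and noisy traces", {
  t <- seq(0, 2000, by = 0.5)
  # trace never exceeding -40: no spikes
  expect_length(detect_spikes(rep(-60, length(t)) + 5 * sin(t / 50), t), 0)
  # two clean excursions
  v <- rep(-70, length(t))
  v[t >= 500 & t <= 503] <- 20
  v[t >= 1500 & t <= 1503] <- 20
  spk <- detect_spikes(v, t)
  expect_length(spk, 2)
  expect_equal(spk, c(500, 1500))
  # noisy spike-like traces: detected count equals the independent
  # hysteresis-based count
  set.seed(7)
  for (i in 1:10) {
    spike_times <- cumsum(runif(15, 60, 180))
    spike_times <- spike_times[spike_times < max(t) - 5]
    v <- rnorm(length(t), -60, 2)
    for (st in spike_times) {
      sel <- abs(t - st) <= 2
      v[sel] <- 15 - 25 * abs(t[sel] - st)
    }
    n_hyst <- oracle_spike_count(v)
    n_det <- length(detect_spikes(v, t, threshold = -20, refractory = 2))
    expect_equal(n_det, n_hyst)
    expect_equal(n_det, length(spike_times))
  }
})

test_that("spike trains are strictly increasing with the refractory guard", {
  tr <- simulate_network(list(cell_nap(-65.5), cell_simple(-58.4)),
                         config = sim_config(duration = 30000, settle = 0))
  for (spk in tr$spikes) {
    expect_false(is.unsorted(spk, strictly = TRUE))
    if (length(spk) > 1) expect_gte(min(diff(spk)), 2)
    expect_true(all(spk >= 0 & spk <= 30000))
  }
})

test_that("blow-up diagnostics name the offending neuron", {
  # a nonsensical initial state far outside the physical range
  p <- data.frame(has_nap = c(FALSE, FALSE), e_l = c(-70, 1e5),
                  g_l = c(1, -0))
  st <- cbind(v = c(-70, 9e307), h_na = 1, h_nap = 1, m_k = 0, s = 0)
  expect_error(
    simulate_network(p, st, config = sim_config(duration = 10, settle = 0)),
    "neuron 2")
})

test_that("two-cell driver reproduces the benchmark uncoupled regimes", {
  run <- run_two_cell(cell_nap(-69), cell_simple(-59.3), coupling = "none",
                      settle = 20000, analysis = 60000)
  expect_equal(run$summary$regime, c("bursting", "tonic"))
  expect_equal(run$summary$frequency_hz[1], 0.2, tolerance = 0.2)
  run2 <- run_two_cell(cell_nap(-72.2), cell_simple(-59.6), coupling = "none",
                       settle = 20000, analysis = 60000)
  expect_equal(run2$summary$regime, c("silent", "silent"))
  expect_equal(run2$summary$resting_mv, c(-71, -57), tolerance = 0.03)
})

test_that("a homogeneous sub-threshold population stays silent", {
  spec <- population_spec(n = 10, n_nap = 10, e_l1_sd = 0, e_l2_sd = 0,
                          g_l_sd = 0, g_nap_sd = 0, e_l1_mean = -74)
  run <- run_population(spec, seed = 1, settle = 5000, duration = 20000)
  expect_equal(run$label, "none")
  expect_lt(mean(run$activity$rate), 0.1)
})
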