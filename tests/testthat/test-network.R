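test_that("gap currents follow pairwise potential differences and conserve charge", {
  g <- gap_matrix(matrix(c(0, 0.1, 0.1, 0), 2, 2))
  expect_equal(gap_currents(c(-60, -70), g), c(-1, 1))
  expect_equal(gap_currents(c(-65, -65), g), c(0, 0))
  # zero-sum over any symmetric matrix and any voltages
  set.seed(1)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    m <- matrix(runif(n * n), n, n) * (runif(n * n) < 0.4)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    v <- runif(n, -80, -40)
    cur <- gap_currents(v, gap_matrix(m))
    expect_equal(sum(cur), 0, tolerance = 1e-10)
  }
})

test_that("asymmetric or negative gap matrices are rejected", {
  m <- matrix(c(0, 0.1, 0.2, 0), 2, 2)
  expect_error(gap_matrix(m), "symmetric")
  expect_error(gap_matrix(matrix(c(0.1, 0, 0, 0), 2, 2)), "diagonal")
  expect_error(gap_matrix(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
})

test_that("synaptic currents scale with gate, weight and driving force", {
  syn <- syn_matrix(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))  # 1 -> 2
  expect_equal(syn_currents(c(-60, -60), c(0, 0), syn), c(0, 0))
  expect_equal(syn_currents(c(-60, 0), c(0.5, 0), syn), c(0, 0))  # at reversal
  expect_equal(syn_currents(c(-40, -60), c(0.5, 0), syn), c(0, -30))
})

test_that("connectivity sampling honors the edge probabilities", {
  expect_true(all(sample_gap_connectivity(10, 0, 0.1, seed = 1) == 0))
  expect_true(all(sample_syn_connectivity(10, 0, 1, seed = 1) == 0))
  g1 <- sample_gap_connectivity(3, 1, 0.2, seed = 1)
  expect_equal(sum(g1 > 0), 6)            # 3 pairs, symmetric entries
  expect_equal(unclass(g1), t(unclass(g1)), ignore_attr = TRUE)
  s1 <- sample_syn_connectivity(3, 1, 1.5, seed = 1)
  expect_equal(sum(s1 > 0), 6)            # 6 ordered pairs
  # binomial edge-count statistics over repeated draws
  n_pairs <- 100 * 99 / 2
  counts <- vapply(1:200, function(s)
    sum(sample_gap_connectivity(100, 0.3, 0.1, seed = s) > 0) / 2, numeric(1))
  se <- sqrt(200 * n_pairs * 0.3 * 0.7) / 200
  expect_lt(abs(mean(counts) - 0.3 * n_pairs), 3 * se)
  dcounts <- vapply(1:200, function(s)
    sum(sample_syn_connectivity(100, 0.1, 1, seed = s + 500) > 0), numeric(1))
  n_ord <- 100 * 99
  se_d <- sqrt(200 * n_ord * 0.1 * 0.9) / 200
  expect_lt(abs(mean(dcounts) - 0.1 * n_ord), 3 * se_d)
})

test_that("population sampling respects the subpopulation structure", {
  spec <- population_spec()
  pop <- sample_population(spec, seed = 3)
  expect_equal(sum(pop$params$has_nap), 40)
  expect_true(all(pop$params$g_nap[!pop$params$has_nap] == 0))
  expect_true(all(pop$params$g_l >= 0))
  expect_true(all(abs(pop$params$e_l[1:40] + 74) <= 3 * 14.8))
  # zero-SD spec collapses each subpopulation onto its mean
  spec0 <- population_spec(e_l1_sd = 0, e_l2_sd = 0, g_l_sd = 0, g_nap_sd = 0)
  pop0 <- sample_population(spec0, seed = 4)
  expect_true(all(pop0$params$e_l[1:40] == -74))
  expect_true(all(pop0$params$e_l[41:100] == -70))
  expect_true(all(pop0$params$g_l == 1))
  expect_true(all(pop0$params$g_nap[1:40] == 4))
  # sampled means converge on the specified means across seeds
  m <- vapply(1:100, function(s)
    mean(sample_population(spec, seed = s)$params$e_l[1:40]), numeric(1))
  se <- 14.8 / sqrt(100 * 40)
  expect_lt(abs(mean(m) + 74), 3 * se)
})

test_that("aggregate coupling matches the N p strength product and inverts", {
  expect_equal(aggregate_coupling(100, 0.3, 0.2), 6)
  expect_equal(aggregate_coupling(100, 0.1, 1.5), 15)
  expect_equal(per_edge_strength(aggregate_coupling(100, 0.3, 0.123), 100, 0.3),
               0.123)
  expect_error(per_edge_strength(6, 100, 0), "undefined")
})

test_that("population serialization round trips through the edge lists", {
  pop <- sample_population(population_spec(n = 20, n_nap = 8, g_gap = 0.1,
                                           w_syn = 1.3), seed = 5)
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  ge <- read.delim(file.path(dir, "gap_edges.tsv"))
  m <- matrix(0, 20, 20)
  m[cbind(ge$i, ge$j)] <- ge$g_gap
  m <- m + t(m)
  expect_equal(m, unclass(pop$gap), ignore_attr = TRUE)
  se <- read.delim(file.path(dir, "syn_edges.tsv"))
  ms <- matrix(0, 20, 20)
  ms[cbind(se$i, se$j)] <- se$w_syn
  expect_equal(ms, unclass(pop$syn), ignore_attr = TRUE)
  np <- read.delim(file.path(dir, "neurons.tsv"))
  expect_equal(np$e_l, pop$params$e_l)
})

test_that("stronger gap coupling equilibrates a silent pair's potentials", {
  cells <- list(cell_nap(-71.4), cell_simple(-59.6))
  dv <- vapply(c(0.02, 0.05, 0.1, 0.2), function(g) {
    tr <- simulate_network(cells,
                           gap = gap_matrix(matrix(c(0, g, g, 0), 2, 2)),
                           config = sim_config(duration = 22000,
                                               settle = 20000,
                                               record_v = TRUE))
    keep <- tr$time >= 20000
    mean(abs(tr$v[keep, 1] - tr$v[keep, 2]))
  }, numeric(1))
  expect_true(all(diff(dv) < 0))
})
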