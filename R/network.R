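#' Gap-junction conductance matrix
#'
#' Validates and tags an N x N matrix of gap-junction conductances (nS).
#' Electrical coupling is bidirectional, so the matrix must be symmetric with
#' zero diagonal and nonnegative entries.
#'
#' @param m Numeric N x N matrix of conductances (nS).
#' @return The matrix with class `gap_matrix`.
#' @export
gap_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m), nrow(m) == ncol(m))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
    stop("invalid gap matrix: electrical coupling is bidirectional, the ",
         "conductance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("invalid gap matrix: diagonal must be zero")
  if (any(m < 0)) stop("invalid gap matrix: conductances must be nonnegative")
  structure(m, class = c("gap_matrix", "matrix", "array"))
}

#' Chemical synaptic weight matrix
#'
#' Validates and tags an N x N matrix of synaptic weights, entry `[i, j]`
#' scaling the unitary conductance (1 nS, reversal 0 mV) of the connection
#' from neuron i onto neuron j. Connections are unidirectional: no symmetry
#' is required (nor forbidden).
#'
#' @param m Numeric N x N matrix of dimensionless weights.
#' @return The matrix with class `syn_matrix`.
#' @export
syn_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m), nrow(m) == ncol(m))
  if (any(diag(m) != 0)) stop("invalid syn matrix: diagonal must be zero")
  if (any(m < 0)) stop("invalid syn matrix: weights must be nonnegative")
  structure(m, class = c("syn_matrix", "matrix", "array"))
}

#' Gap-junction coupling drive
#'
#' For each neuron j returns `sum_i g_ij * (V_i - V_j)` (pA), the ohmic
#' current flowing into j from its electrically coupled neighbours. The
#' membrane equation applies this with depolarizing sign: coupling pulls each
#' neuron's potential toward its neighbours', equilibrating membrane
#' potentials. Pairwise terms are antisymmetric, so the drives sum to zero
#' over the network at every instant.
#'
#' @param v Vector of membrane potentials (mV).
#' @param gap A [gap_matrix()].
#' @return Vector of drives (pA), one per neuron.
#' @export
gap_currents <- function(v, gap) {
  if (!inherits(gap, "gap_matrix")) gap <- gap_matrix(gap)
  stopifnot(length(v) == nrow(gap))
  # c_j = sum_i g_ij v_i - v_j sum_i g_ij
  as.vector(crossprod(gap, v)) - v * colSums(gap)
}

#' Chemical synaptic currents
#'
#' For each target neuron j returns
#' `I_syn_j = g_syn * (sum_i w_ij * s_i) * (V_j - e_syn)` (pA), the AMPA-like
#' current gated by the presynaptic output variables `s`. It enters the
#' membrane equation with a minus sign, so with the 0 mV reversal it
#' depolarizes any target below 0 mV.
#'
#' @param v Vector of membrane potentials (mV).
#' @param s Vector of presynaptic gate values in \[0, 1\].
#' @param syn A [syn_matrix()].
#' @param g_syn Unitary synaptic conductance (nS), default 1.
#' @param e_syn Synaptic reversal potential (mV), default 0.
#' @return Vector of currents (pA, outward positive), one per neuron.
#' @export
syn_currents <- function(v, s, syn, g_syn = 1, e_syn = 0) {
  if (!inherits(syn, "syn_matrix")) syn <- syn_matrix(syn)
  stopifnot(length(v) == nrow(syn), length(s) == nrow(syn),
            all(s >= 0 & s <= 1))
  g_syn * as.vector(crossprod(syn, s)) * (v - e_syn)
}

#' Sample random gap-junction connectivity
#'
#' Each unordered pair of neurons is independently connected with probability
#' `p_gap`; connected pairs share a bidirectional junction of conductance
#' `g_gap`. The default probability 0.3 matches the incidence of electrical
#' coupling measured between neighbouring Shox2 spinal interneurons.
#'
#' @param n Number of neurons.
#' @param p_gap Connection probability per pair, in \[0, 1\].
#' @param g_gap Junction conductance (nS).
#' @param seed Optional integer seed for reproducibility.
#' @return A [gap_matrix()].
#' @export
sample_gap_connectivity <- function(n, p_gap = 0.3, g_gap = 0.1, seed = NULL) {
  stopifnot(n >= 1, p_gap >= 0, p_gap <= 1, g_gap >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  if (n > 1) {
    up <- upper.tri(m)
    m[up] <- g_gap * (runif(sum(up)) < p_gap)
    m <- m + t(m)
  }
  gap_matrix(m)
}

#' Sample random chemical connectivity
#'
#' Each ordered pair (i -> j), i != j, is independently connected with
#' probability `p_syn` and weight `w_syn`. The default probability 0.1
#' matches the measured incidence of excitatory chemical connections between
#' Shox2 interneurons. Reciprocal pairs may arise by chance; each single
#' synapse is unidirectional.
#'
#' @param n Number of neurons.
#' @param p_syn Connection probability per ordered pair, in \[0, 1\].
#' @param w_syn Synaptic weight (dimensionless, scales the 1 nS unitary
#'   conductance).
#' @param seed Optional integer seed.
#' @return A [syn_matrix()].
#' @export
sample_syn_connectivity <- function(n, p_syn = 0.1, w_syn = 1, seed = NULL) {
  stopifnot(n >= 1, p_syn >= 0, p_syn <= 1, w_syn >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- w_syn * matrix(runif(n * n) < p_syn, n, n)
  diag(m) <- 0
  syn_matrix(m)
}

#' Aggregate coupling measure
#'
#' The expected total electrical or chemical input per neuron:
#' `G = N * p_gap * g_gap` (nS) for gap junctions, `W = N * p_syn * w_syn`
#' (dimensionless) for chemical synapses. These aggregates index the
#' two-parameter regime diagrams of populational activity.
#'
#' @param n Population size.
#' @param p Connection probability.
#' @param strength Per-edge strength (`g_gap` in nS or `w_syn`).
#' @return The aggregate coupling (G or W).
#' @examples
#' aggregate_coupling(100, 0.3, 0.2)  # G = 6 nS
#' aggregate_coupling(100, 0.1, 1.5)  # W = 15
#' @export
aggregate_coupling <- function(n, p, strength) {
  stopifnot(n > 0, p >= 0, p <= 1, strength >= 0)
  n * p * strength
}

#' Per-edge strength for a target aggregate coupling
#'
#' Inverse of [aggregate_coupling()]: the per-edge strength that yields a
#' desired aggregate `G` or `W` at population size `n` and connection
#' probability `p`. Undefined for `p = 0`.
#'
#' @param aggregate Target aggregate coupling (G in nS or W).
#' @param n Population size.
#' @param p Connection probability (> 0).
#' @return Per-edge strength (`g_gap` or `w_syn`).
#' @export
per_edge_strength <- function(aggregate, n, p) {
  stopifnot(n > 0, aggregate >= 0)
  if (!is.numeric(p) || p <= 0)
    stop("per-edge strength is undefined for connection probability p = 0")
  aggregate / (n * p)
}

#' Distributional description of a heterogeneous neuron population
#'
#' Specifies a population of `n` neurons split into `n_nap` conditional
#' bursters carrying the persistent sodium current and `n - n_nap` simple
#' spiking neurons. Heterogeneity comes from normal distributions of the leak
#' reversal potential (separate means/SDs per subpopulation), the leak
#' conductance, and (for the INaP subpopulation) the INaP conductance.
#' Connectivity is random with pairwise probabilities `p_gap` (bidirectional
#' gap junctions) and `p_syn` (unidirectional excitatory synapses). Defaults
#' are the standard populational conditions: n = 100, n_nap = 40,
#' E_L = -74 +/- 14.8 mV (INaP subpopulation) and -70 +/- 14 mV (simple),
#' g_L = 1 +/- 0.2 nS, g_NaP = 4 +/- 0.8 nS, T_hmax = 9 s, p_gap = 0.3,
#' p_syn = 0.1.
#'
#' @param n Population size.
#' @param n_nap Number of neurons carrying INaP (0 <= n_nap <= n).
#' @param e_l1_mean,e_l1_sd Leak reversal mean/SD (mV) for the INaP
#'   subpopulation.
#' @param e_l2_mean,e_l2_sd Leak reversal mean/SD (mV) for the simple
#'   subpopulation.
#' @param g_l_mean,g_l_sd Leak conductance mean/SD (nS).
#' @param g_nap_mean,g_nap_sd INaP conductance mean/SD (nS).
#' @param t_hmax Maximal INaP inactivation time constant (ms).
#' @param p_gap,p_syn Connection probabilities.
#' @param g_gap Gap-junction conductance (nS).
#' @param w_syn Chemical synaptic weight.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 100, n_nap = 40,
                            e_l1_mean = -74, e_l1_sd = 14.8,
                            e_l2_mean = -70, e_l2_sd = 14,
                            g_l_mean = 1, g_l_sd = 0.2,
                            g_nap_mean = 4, g_nap_sd = 0.8,
                            t_hmax = 9000, p_gap = 0.3, p_syn = 0.1,
                            g_gap = 0, w_syn = 0) {
  stopifnot(n >= 1, n_nap >= 0, n_nap <= n,
            e_l1_sd >= 0, e_l2_sd >= 0, g_l_sd >= 0, g_nap_sd >= 0,
            t_hmax > 0, p_gap >= 0, p_gap <= 1, p_syn >= 0, p_syn <= 1,
            g_gap >= 0, w_syn >= 0)
  structure(list(n = n, n_nap = n_nap,
                 e_l1_mean = e_l1_mean, e_l1_sd = e_l1_sd,
                 e_l2_mean = e_l2_mean, e_l2_sd = e_l2_sd,
                 g_l_mean = g_l_mean, g_l_sd = g_l_sd,
                 g_nap_mean = g_nap_mean, g_nap_sd = g_nap_sd,
                 t_hmax = t_hmax, p_gap = p_gap, p_syn = p_syn,
                 g_gap = g_gap, w_syn = w_syn),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> N = %d (%d with INaP)\n", x$n, x$n_nap))
  cat(sprintf("  E_L: %g +/- %g mV (INaP) | %g +/- %g mV (simple)\n",
              x$e_l1_mean, x$e_l1_sd, x$e_l2_mean, x$e_l2_sd))
  cat(sprintf("  g_L = %g +/- %g nS; g_NaP = %g +/- %g nS; T_hmax = %g ms\n",
              x$g_l_mean, x$g_l_sd, x$g_nap_mean, x$g_nap_sd, x$t_hmax))
  cat(sprintf("  p_gap = %g (g_gap = %g nS, G = %g); p_syn = %g (w_syn = %g, W = %g)\n",
              x$p_gap, x$g_gap, aggregate_coupling(x$n, x$p_gap, x$g_gap),
              x$p_syn, x$w_syn, aggregate_coupling(x$n, x$p_syn, x$w_syn)))
  invisible(x)
}

# Normal draws truncated at mean +/- 3 SD (redraw outside the band). The
# stated population SDs are large enough (20% of mean, and ~15 mV for E_L)
# that untruncated draws occasionally produce non-physical parameters.
rnorm_trunc <- function(n, mean, sd, width = 3) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > width * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > width * sd
  }
  x
}

#' Sample neuron parameters, initial states and connectivity of a population
#'
#' Draws the heterogeneous parameters described by a [population_spec()]:
#' the first `n_nap` neurons get INaP with conductance ~ Normal(mean, SD) and
#' leak reversal from the INaP-subpopulation distribution; the rest get the
#' simple-subpopulation leak reversal; every neuron gets a leak conductance ~
#' Normal(mean, SD). Normal draws are truncated at +/- 3 SD and conductances
#' floored at 0. Initial membrane potentials are Normal(E_L, 5 mV), gates
#' start at steady state for the initial potential, synaptic gates at 0; the
#' settling period of a simulation absorbs residual dependence on these
#' choices. Connectivity is sampled per [sample_gap_connectivity()] and
#' [sample_syn_connectivity()].
#'
#' @param spec A [population_spec()].
#' @param seed Optional integer seed (one seed fixes parameters, initial
#'   states and connectivity).
#' @return A list of class `population` with elements `params` (data frame:
#'   neuron, has_nap, e_l, g_l, g_nap, t_hmax), `state0` (n x 5 matrix:
#'   v, h_na, h_nap, m_k, s), `gap`, `syn`, and `spec`.
#' @export
sample_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  has_nap <- seq_len(n) <= spec$n_nap
  e_l <- numeric(n)
  e_l[has_nap] <- rnorm_trunc(spec$n_nap, spec$e_l1_mean, spec$e_l1_sd)
  e_l[!has_nap] <- rnorm_trunc(n - spec$n_nap, spec$e_l2_mean, spec$e_l2_sd)
  g_l <- pmax(0, rnorm_trunc(n, spec$g_l_mean, spec$g_l_sd))
  g_nap <- ifelse(has_nap,
                  pmax(0, rnorm_trunc(n, spec$g_nap_mean, spec$g_nap_sd)), 0)
  v0 <- rnorm(n, e_l, 5)
  state0 <- cbind(v = v0,
                  h_na = gate_inf("h_na", v0),
                  h_nap = gate_inf("h_nap", v0),
                  m_k = gate_inf("m_k", v0),
                  s = 0)
  gap <- sample_gap_connectivity(n, spec$p_gap, spec$g_gap)
  syn <- sample_syn_connectivity(n, spec$p_syn, spec$w_syn)
  params <- data.frame(neuron = seq_len(n), has_nap = has_nap, e_l = e_l,
                       g_l = g_l, g_nap = g_nap, t_hmax = spec$t_hmax)
  structure(list(params = params, state0 = state0, gap = gap, syn = syn,
                 spec = spec),
            class = "population")
}

#' Write a sampled population to plain-text tables
#'
#' Serializes the sampled neuron parameters and the two connectivity
#' structures as tab-separated files (`neurons.tsv`; `gap_edges.tsv` with
#' columns i, j, g_gap over i < j; `syn_edges.tsv` with columns i, j, w_syn)
#' for reproducibility audits.
#'
#' @param pop A sampled `population` from [sample_population()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("neurons.tsv", "gap_edges.tsv", "syn_edges.tsv"))
  utils::write.table(pop$params, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  ge <- which(upper.tri(pop$gap) & pop$gap > 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(i = ge[, 1], j = ge[, 2], g_gap = pop$gap[ge]),
    paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
  se <- which(pop$syn > 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(i = se[, 1], j = se[, 2], w_syn = pop$syn[se]),
    paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}
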