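#' Biophysical parameters of one model neuron
#'
#' Constructs the parameter set of a single-compartment Hodgkin-Huxley style
#' neuron with fast sodium, delayed-rectifier potassium and leak currents,
#' plus an optional persistent (slowly inactivating) sodium current (INaP)
#' that turns the cell into a conditional burster. The operating regime of an
#' isolated neuron (silent, bursting or tonic spiking) is set chiefly by its
#' leak reversal potential `e_l`.
#'
#' Units are mV, ms, nS and pF throughout, so that conductance times driving
#' force is in pA and pA/pF is mV/ms.
#'
#' @param e_l Leak reversal potential (mV).
#' @param has_nap Does the neuron carry the persistent sodium current?
#' @param g_nap Maximal INaP conductance (nS); forced to 0 when
#'   `has_nap = FALSE`.
#' @param g_na,g_k,g_l Maximal fast-sodium, delayed-rectifier and leak
#'   conductances (nS).
#' @param c Membrane capacitance (pF).
#' @param e_na,e_k Sodium and potassium reversal potentials (mV).
#' @param t_hmax Maximal INaP inactivation time constant (ms); the slow
#'   variable that paces intrinsic bursting (default 9000 ms = 9 s).
#' @return An object of class `neuron_params`.
#' @examples
#' burster <- neuron_params(e_l = -69)               # intrinsic burster
#' simple  <- neuron_params(e_l = -59.3, has_nap = FALSE)  # tonic spiker
#' @export
neuron_params <- function(e_l, has_nap = TRUE, g_nap = 4, g_na = 80, g_k = 100,
                          g_l = 1, c = 40, e_na = 55, e_k = -80, t_hmax = 9000) {
  stopifnot(is.numeric(e_l), length(e_l) == 1L, is.finite(e_l),
            isTRUE(has_nap) || isFALSE(has_nap),
            g_nap >= 0, g_na >= 0, g_k >= 0, g_l >= 0, c > 0, t_hmax > 0)
  if (!has_nap) g_nap <- 0
  structure(list(c = c, g_na = g_na, g_k = g_k, g_l = g_l, g_nap = g_nap,
                 e_na = e_na, e_k = e_k, e_l = e_l, t_hmax = t_hmax,
                 has_nap = has_nap),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> %s neuron\n",
              if (x$has_nap) "INaP (conditional burster)" else "simple"))
  cat(sprintf("  E_L = %g mV; g_Na = %g, g_K = %g, g_L = %g, g_NaP = %g nS\n",
              x$e_l, x$g_na, x$g_k, x$g_l, x$g_nap))
  cat(sprintf("  C = %g pF; E_Na = %g, E_K = %g mV; T_hmax = %g ms\n",
              x$c, x$e_na, x$e_k, x$t_hmax))
  invisible(x)
}

#' Dynamical state of one model neuron
#'
#' The integrated state is (V, h_na, h_nap, m_k, s): membrane potential, the
#' two sodium inactivation gates, potassium activation and the synaptic
#' output gate. The sodium activation gates are instantaneous and evaluated
#' as their steady states at the current V, so they are not part of the
#' state. By default the gates are initialized at their steady-state values
#' for the given V and the synaptic gate at 0.
#'
#' @param v Membrane potential (mV).
#' @param h_na,h_nap,m_k Gating variables in \[0, 1\]; default steady state
#'   at `v`.
#' @param s Synaptic output gate in \[0, 1\]; default 0.
#' @return An object of class `neuron_state` (named numeric vector).
#' @export
neuron_state <- function(v, h_na = gate_inf("h_na", v),
                         h_nap = gate_inf("h_nap", v),
                         m_k = gate_inf("m_k", v), s = 0) {
  stopifnot(is.finite(v),
            h_na >= 0, h_na <= 1, h_nap >= 0, h_nap <= 1,
            m_k >= 0, m_k <= 1, s >= 0, s <= 1)
  structure(c(v = v, h_na = h_na, h_nap = h_nap, m_k = m_k, s = s),
            class = "neuron_state")
}

#' Ionic currents of one neuron
#'
#' Evaluates the four intrinsic currents at a given state: fast sodium
#' (cubic instantaneous activation times inactivation), persistent sodium
#' (instantaneous activation times slow inactivation; identically 0 for
#' neurons without INaP), delayed-rectifier potassium (fourth-power
#' activation, no inactivation) and ohmic leak. Each current vanishes at its
#' reversal potential.
#'
#' @param state A [neuron_state()].
#' @param params A [neuron_params()].
#' @return Named numeric vector `c(i_na, i_nap, i_k, i_l)` in pA
#'   (outward positive).
#' @export
ionic_currents <- function(state, params) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  v <- state[["v"]]
  i_na <- params$g_na * gate_inf("m_na", v)^3 * state[["h_na"]] * (v - params$e_na)
  i_nap <- if (params$has_nap)
    params$g_nap * gate_inf("m_nap", v) * state[["h_nap"]] * (v - params$e_na)
  else 0
  i_k <- params$g_k * state[["m_k"]]^4 * (v - params$e_k)
  i_l <- params$g_l * (v - params$e_l)
  c(i_na = i_na, i_nap = i_nap, i_k = i_k, i_l = i_l)
}

#' Time derivative of the full single-neuron state
#'
#' Right-hand side of the membrane and gating equations for one neuron given
#' its coupling inputs. The membrane equation is
#' `C dV/dt = -(I_Na + I_NaP + I_K + I_L + I_syn) + I_gap_drive`,
#' where `i_gap_drive` is the gap-junction drive `sum_i g_ij (V_i - V_j)`
#' entered with depolarizing sign (coupling pulls V toward the neighbours'
#' potentials) and `i_syn` is the chemical synaptic current (subtracted, so
#' it depolarizes for V below the 0 mV reversal). Each non-instantaneous gate
#' relaxes to its steady state with its voltage-dependent time constant; the
#' synaptic gate follows [syn_gate_derivative()].
#'
#' This pure-R evaluation is the reference implementation; production
#' integration runs through the compiled core in [simulate_network()].
#'
#' @inheritParams ionic_currents
#' @param i_gap_drive Gap-junction drive (pA), as returned by
#'   [gap_currents()].
#' @param i_syn Chemical synaptic current (pA), as returned by
#'   [syn_currents()].
#' @return Named numeric vector of derivatives (per ms) in state order.
#' @export
state_derivative <- function(state, params, i_gap_drive = 0, i_syn = 0) {
  stopifnot(is.finite(i_gap_drive), is.finite(i_syn))
  v <- state[["v"]]
  cur <- ionic_currents(state, params)
  dv <- (-(sum(cur) + i_syn) + i_gap_drive) / params$c
  dh_na <- (gate_inf("h_na", v) - state[["h_na"]]) / gate_tau("h_na", v)
  dh_nap <- if (params$has_nap)
    (gate_inf("h_nap", v) - state[["h_nap"]]) /
      gate_tau("h_nap", v, params$t_hmax)
  else 0
  dm_k <- (gate_inf("m_k", v) - state[["m_k"]]) / gate_tau("m_k", v)
  ds <- syn_gate_derivative(state[["s"]], v)
  c(v = dv, h_na = dh_na, h_nap = dh_nap, m_k = dm_k, s = ds)
}
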