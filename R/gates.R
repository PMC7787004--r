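#' @useDynLib burstnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd setNames
NULL

# Channel kinetics registry. Each gate has a Boltzmann steady state
#   x_inf(V) = 1 / (1 + exp(sign * (V - vhalf) / k))
# with sign = -1 for activation gates (increasing in V) and +1 for
# inactivation gates (decreasing in V), and -- for non-instantaneous gates --
# a bell-shaped time constant
#   tau_x(V) = tau_max / cosh((V - vhalf) / k_tau)
# peaking at the half-(in)activation voltage. Activation of both sodium
# channels is instantaneous (tau = 0): m_na and m_nap are evaluated
# algebraically as m_inf(V) at every step and are not state variables.
# The delayed-rectifier channel has no inactivation (h_k == 1).
.gates <- list(
  m_na  = list(vhalf = -42.5, k = 6.5,  sign = -1, instantaneous = TRUE,
               tau_max = NA,   k_tau = NA),
  h_na  = list(vhalf = -65.5, k = 10.2, sign = +1, instantaneous = FALSE,
               tau_max = 35.2, k_tau = 12.8),
  m_nap = list(vhalf = -52.0, k = 3.2,  sign = -1, instantaneous = TRUE,
               tau_max = NA,   k_tau = NA),
  h_nap = list(vhalf = -57.0, k = 5.0,  sign = +1, instantaneous = FALSE,
               tau_max = NA,   k_tau = 8.0),  # tau_max is T_hmax, caller-supplied
  m_k   = list(vhalf = -34.5, k = 5.0,  sign = -1, instantaneous = FALSE,
               tau_max = 10.0, k_tau = 10.0)
)

# Chemical synapse constants (AMPA-like): first-order gate
#   ds/dt = alpha_s * s_inf(V_pre) * (1 - s) - s / tau_s
.syn_const <- list(alpha_s = 1, tau_s = 15, v_s12 = -20, k_s = 2,
                   g_syn = 1, e_syn = 0)

.check_gate <- function(gate) {
  if (!is.character(gate) || length(gate) != 1L || !gate %in% names(.gates))
    stop("unknown gate '", paste(gate, collapse = ","),
         "'; must be one of: ", paste(names(.gates), collapse = ", "))
  .gates[[gate]]
}

#' Steady-state (in)activation of a gating variable
#'
#' Voltage-dependent steady state of one of the five channel gating variables
#' (`"m_na"`, `"h_na"`, `"m_nap"`, `"h_nap"`, `"m_k"`), a Boltzmann function
#' of membrane potential. Activation gates increase with depolarization,
#' inactivation gates decrease; values always lie in \[0, 1\].
#'
#' @param gate Gate identifier, one of `"m_na"`, `"h_na"`, `"m_nap"`,
#'   `"h_nap"`, `"m_k"`.
#' @param v Membrane potential (mV); may be a vector.
#' @return Steady-state fraction in \[0, 1\], same length as `v`.
#' @examples
#' gate_inf("m_na", -42.5)   # 0.5 at the half-activation voltage
#' gate_inf("h_nap", -57)    # 0.5 at the half-inactivation voltage
#' @export
gate_inf <- function(gate, v) {
  g <- .check_gate(gate)
  stopifnot(is.numeric(v), all(is.finite(v)))
  1 / (1 + exp(g$sign * (v - g$vhalf) / g$k))
}

#' Voltage-dependent time constant of a gating variable
#'
#' Time constant of one of the non-instantaneous gates (`"h_na"`, `"h_nap"`,
#' `"m_k"`): a symmetric, bell-shaped (reciprocal-cosh) profile peaking at the
#' gate's half-voltage. The peak values are 35.2 ms for `h_na`, `t_hmax` for
#' `h_nap` (the slow inactivation of the persistent sodium current, typically
#' seconds) and 10 ms for `m_k`. Requesting an instantaneous gate (`m_na`,
#' `m_nap`) is an error: those gates track their steady state exactly.
#'
#' @inheritParams gate_inf
#' @param t_hmax Maximal inactivation time constant of the persistent sodium
#'   current (ms); used only for `gate = "h_nap"`. Default 9000 ms.
#' @return Time constant (ms), strictly positive, same length as `v`.
#' @examples
#' gate_tau("h_na", -65.5)          # 35.2 ms at the peak
#' gate_tau("h_nap", -57, 9000)     # equals t_hmax at the peak
#' @export
gate_tau <- function(gate, v, t_hmax = 9000) {
  g <- .check_gate(gate)
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (g$instantaneous)
    stop("gate '", gate, "' is instantaneous (tau = 0); it has no time constant")
  tau_max <- if (gate == "h_nap") {
    stopifnot(is.numeric(t_hmax), length(t_hmax) == 1L, t_hmax > 0)
    t_hmax
  } else g$tau_max
  tau_max / cosh((v - g$vhalf) / g$k_tau)
}

#' Steady-state activation of the synaptic output gate
#'
#' Boltzmann activation of the presynaptic transmitter-release gate `s`
#' (half-activation -20 mV, slope 2 mV), used in the first-order kinetic
#' scheme of the excitatory chemical synapse.
#'
#' @param v Presynaptic membrane potential (mV); may be a vector.
#' @return Fraction in \[0, 1\].
#' @export
syn_s_inf <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  1 / (1 + exp(-(v - .syn_const$v_s12) / .syn_const$k_s))
}

#' Rate of change of the synaptic output gate
#'
#' First-order activation scheme for the chemical-synapse gate:
#' `ds/dt = alpha_s * s_inf(V) * (1 - s) - s / tau_s` with `alpha_s` = 1/ms
#' and `tau_s` = 15 ms. With the presynaptic cell clamped depolarized
#' (`s_inf` = 1) the gate settles at `alpha_s * tau_s / (1 + alpha_s * tau_s)`
#' = 15/16; clamped hyperpolarized it decays to 0 with time constant 15 ms.
#'
#' @param s Current gate value in \[0, 1\].
#' @param v Presynaptic membrane potential (mV).
#' @return Rate of change (per ms).
#' @export
syn_gate_derivative <- function(s, v) {
  stopifnot(is.numeric(s), all(s >= 0 & s <= 1))
  .syn_const$alpha_s * syn_s_inf(v) * (1 - s) - s / .syn_const$tau_s
}
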