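#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane parameters shared by all populations (A, B1, B2).  Potentials are
#' in arbitrary consistent units; the defaults use a normalized scale with
#' resting potential 0 and threshold 1.  The defaults are chosen so that a
#' unit-amplitude current pulse of 5.5 ms drives a short burst of 2-4 spikes
#' in an A neuron, which is the encoding regime the network's coincidence
#' learning relies on.
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_rest Resting potential.
#' @param v_thresh Firing threshold; must exceed \code{v_rest}.
#' @param v_reset Post-spike reset potential.
#' @param r_in Input resistance (potential units per unit current).
#' @param t_refr Absolute refractory period (ms).
#'
#' @return An object of class \code{"neuron_params"}.
#' @export
#' @examples
#' np <- neuron_params()
#' np$tau_m
neuron_params <- function(tau_m = 10, v_rest = 0, v_thresh = 1,
                          v_reset = 0, r_in = 13, t_refr = 1) {
  stopifnot(tau_m > 0, v_thresh > v_rest, t_refr >= 0, r_in > 0)
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, r_in = r_in, t_refr = t_refr),
            class = "neuron_params")
}

#' Network architecture parameters
#'
#' Defines the tonotopic network: number of frequency channels, the lateral
#' fan-out of the plastic B1 -> B2 projections, and the distance-dependent
#' transmission delay law \eqn{d = d_0 + |x - y| \nu} replacing hardware
#' delay-relay neurons by an explicit event queue.
#'
#' @param n_channels Number of tonotopic channels (default 32).
#' @param fan_out Number of channels reached on each side by the lateral
#'   plastic projections (default 14); clipped at the tonotopic edges, no
#'   wraparound.
#' @param nu Propagation time per channel separation (ms/channel).
#' @param d0 Fixed propagation offset added to every synaptic delay (ms).
#' @param w_a_b1 A -> B1 same-channel excitatory strength (potential jump).
#' @param w_a_b2 A -> B2 same-channel excitatory strength.
#' @param w_inh B1 -> B2 inhibitory strength (positive number; applied as a
#'   negative potential jump).
#' @param w_plastic_max Potential jump delivered by a lateral plastic synapse
#'   at full efficacy (w = 1).
#' @param inhibition_mode One of \code{"same"} (same-channel B1 -> B2
#'   inhibition, the default minimal topology), \code{"all"} (every B1
#'   inhibits every B2), or \code{"off"}.
#' @param dt Integration step (ms).
#'
#' @return An object of class \code{"network_params"}.
#' @export
network_params <- function(n_channels = 32L, fan_out = 14L, nu = 1,
                           d0 = 1, w_a_b1 = 1.2, w_a_b2 = 0.7,
                           w_inh = 0.25, w_plastic_max = 0.3,
                           inhibition_mode = c("same", "all", "off"),
                           dt = 0.1) {
  inhibition_mode <- match.arg(inhibition_mode)
  n_channels <- as.integer(n_channels)
  fan_out <- as.integer(fan_out)
  if (n_channels < 2L)
    stop("n_channels must be at least 2", call. = FALSE)
  if (fan_out < 1L || fan_out >= n_channels)
    stop("fan_out must satisfy 1 <= fan_out < n_channels", call. = FALSE)
  stopifnot(nu >= 0, d0 >= 0, dt > 0, w_plastic_max >= 0)
  structure(list(n_channels = n_channels, fan_out = fan_out, nu = nu,
                 d0 = d0, w_a_b1 = w_a_b1, w_a_b2 = w_a_b2, w_inh = w_inh,
                 w_plastic_max = w_plastic_max,
                 inhibition_mode = inhibition_mode, dt = dt),
            class = "network_params")
}

#' Bistable plasticity rule parameters
#'
#' Parameters of the spike-driven bistable learning rule at the lateral
#' B1 -> B2 synapses.  Efficacy w is bounded in [0, 1] and, in the absence
#' of presynaptic events, drifts toward one of the two stable values 0 or 1
#' depending on which side of the bistability threshold \code{w_theta} it
#' lies (at exactly \code{w_theta} it drifts down).  Presynaptic spike
#' arrivals trigger jumps gated by the postsynaptic calcium-like activity
#' trace: a recently active postsynaptic cell (ca >= \code{ca_thresh_pot})
#' potentiates, a cell active slightly earlier
#' (\code{ca_thresh_dep} <= ca < \code{ca_thresh_pot}) depresses, and a
#' quiescent cell leaves the synapse untouched.  The gate constants used on
#' the neuromorphic chips are unpublished; these are free parameters.
#'
#' @param w_theta Bistability threshold in (0, 1).
#' @param alpha_up Upward drift rate (1/ms) applied when w > w_theta.
#' @param beta_down Downward drift rate (1/ms) applied when w <= w_theta.
#' @param a_pot Potentiation jump magnitude.
#' @param b_dep Depression jump magnitude.
#' @param ca_thresh_pot Calcium gate above which a pre-spike potentiates.
#' @param ca_thresh_dep Calcium gate above which (and below
#'   \code{ca_thresh_pot}) a pre-spike depresses.
#' @param tau_ca Decay time constant of the postsynaptic calcium trace (ms).
#' @param ca_jump Calcium increment per postsynaptic spike.
#'
#' @return An object of class \code{"plasticity_params"}.
#' @export
plasticity_params <- function(w_theta = 0.5, alpha_up = 5e-4,
                              beta_down = 5e-4, a_pot = 0.2, b_dep = 0.2,
                              ca_thresh_pot = 0.5, ca_thresh_dep = 0.05,
                              tau_ca = 4, ca_jump = 1) {
  stopifnot(w_theta > 0, w_theta < 1, alpha_up >= 0, beta_down >= 0,
            a_pot >= 0, b_dep >= 0, tau_ca > 0,
            ca_thresh_dep >= 0, ca_thresh_pot > ca_thresh_dep)
  structure(list(w_theta = w_theta, alpha_up = alpha_up,
                 beta_down = beta_down, a_pot = a_pot, b_dep = b_dep,
                 ca_thresh_pot = ca_thresh_pot, ca_thresh_dep = ca_thresh_dep,
                 tau_ca = tau_ca, ca_jump = ca_jump),
            class = "plasticity_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters:\n")
  cat(sprintf("  tau_m = %g ms, v_rest = %g, v_thresh = %g, v_reset = %g\n",
              x$tau_m, x$v_rest, x$v_thresh, x$v_reset))
  cat(sprintf("  r_in = %g, t_refr = %g ms\n", x$r_in, x$t_refr))
  invisible(x)
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("Tonotopic network: %d channels, fan-out %d per side\n",
              x$n_channels, x$fan_out))
  cat(sprintf("  delay law: d0 + |x-y|*nu = %g + |x-y|*%g ms\n", x$d0, x$nu))
  cat(sprintf("  weights: A->B1 %g, A->B2 %g, inh %g (%s), plastic max %g\n",
              x$w_a_b1, x$w_a_b2, x$w_inh, x$inhibition_mode,
              x$w_plastic_max))
  cat(sprintf("  dt = %g ms\n", x$dt))
  invisible(x)
}
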