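#' Advance a leaky integrate-and-fire membrane by one step
#'
#' Reference single-neuron update used throughout the simulator (the
#' compiled network core applies the identical rule).  Forward-Euler
#' integration of \eqn{\tau_m dv/dt = (v_{rest} - v) + R_{in} I}; on
#' crossing threshold the neuron emits a spike, resets to \code{v_reset} and
#' becomes refractory for \code{t_refr} ms (membrane clamped at the reset
#' potential, input ignored).
#'
#' @param state List with elements \code{v} (membrane potential) and
#'   \code{refr_ms} (remaining refractory time, ms); use
#'   \code{lif_init(neuron)} for a resting state.
#' @param i_in Input current over this step.
#' @param dt Step size (ms), > 0.
#' @param neuron A \code{\link{neuron_params}} object.
#'
#' @return The updated state; element \code{spike} is \code{TRUE} if a spike
#'   was emitted during this step.
#' @export
#' @examples
#' s <- lif_init(neuron_params())
#' s <- step_lif(s, i_in = 0.5, dt = 0.1, neuron_params())
step_lif <- function(state, i_in, dt, neuron) {
  stopifnot(dt > 0)
  spike <- FALSE
  if (state$refr_ms > 1e-9) {  # tolerance guards against dt accumulation
    state$refr_ms <- state$refr_ms - dt
    state$v <- neuron$v_reset
  } else {
    v <- state$v + dt / neuron$tau_m *
      ((neuron$v_rest - state$v) + neuron$r_in * i_in)
    if (v >= neuron$v_thresh) {
      spike <- TRUE
      v <- neuron$v_reset
      state$refr_ms <- neuron$t_refr
    }
    state$v <- v
  }
  state$spike <- spike
  state
}

#' @rdname step_lif
#' @export
lif_init <- function(neuron) {
  list(v = neuron$v_rest, refr_ms = 0, spike = FALSE)
}

#' Closed-form first-spike latency of a LIF neuron under constant current
#'
#' For constant suprathreshold input from rest the continuous-time membrane
#' crosses threshold at
#' \eqn{t^* = \tau_m \ln(R I / (R I - (v_{thresh} - v_{rest})))};
#' returns \code{Inf} for subthreshold input.  Used as an independent check
#' on the stepped dynamics.
#'
#' @param i_in Constant input current.
#' @param neuron A \code{\link{neuron_params}} object.
#' @return Latency in ms (possibly \code{Inf}).
#' @export
lif_first_spike_time <- function(i_in, neuron) {
  drive <- neuron$r_in * i_in
  gap <- neuron$v_thresh - neuron$v_rest
  if (drive <= gap) return(Inf)
  neuron$tau_m * log(drive / (drive - gap))
}
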