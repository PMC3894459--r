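#' Presynaptic-spike update of a bistable plastic synapse
#'
#' Applies the gated jump of the spike-driven bistable rule when a
#' presynaptic spike arrives at a lateral B1 -> B2 synapse.  The jump is
#' gated by the postsynaptic calcium-like trace at the arrival time:
#' \itemize{
#'   \item \code{ca >= ca_thresh_pot}: the postsynaptic cell fired just
#'     before the arrival (a coincidence) -- potentiate by \code{a_pot};
#'   \item \code{ca_thresh_dep <= ca < ca_thresh_pot}: the postsynaptic cell
#'     fired somewhat earlier, i.e. target-channel activity preceded the
#'     delayed source-channel activity -- depress by \code{b_dep};
#'   \item \code{ca < ca_thresh_dep}: quiescent target -- no change.
#' }
#' The efficacy is clamped to [0, 1] after the jump.
#'
#' @param w Current efficacy in [0, 1].
#' @param ca Postsynaptic calcium trace at the pre-spike arrival time (see
#'   \code{\link{decay_ca}}).
#' @param pp A \code{\link{plasticity_params}} object.
#' @return The updated efficacy.
#' @export
#' @examples
#' on_pre_spike(0.4, ca = 1, plasticity_params(a_pot = 0.3))  # 0.7
on_pre_spike <- function(w, ca, pp = plasticity_params()) {
  stopifnot(w >= 0, w <= 1, ca >= 0)
  if (ca >= pp$ca_thresh_pot) {
    min(1, w + pp$a_pot)
  } else if (ca >= pp$ca_thresh_dep) {
    max(0, w - pp$b_dep)
  } else {
    w
  }
}

#' Bistable drift of synaptic efficacy
#'
#' Between learning events the efficacy drifts toward one of the two stable
#' values: up toward 1 at rate \code{alpha_up} when above the bistability
#' threshold, down toward 0 at rate \code{beta_down} when at or below it
#' (the tie at exactly \code{w_theta} drifts down, matching the "low"
#' initial-state convention).  Both stable values are absorbing, so any
#' efficacy left to drift long enough ends within numerical tolerance of
#' 0 or 1.
#'
#' @param w Current efficacy in [0, 1] (vectorized).
#' @param dt Elapsed drift time (ms), > 0.
#' @param pp A \code{\link{plasticity_params}} object.
#' @return The drifted efficacy, clamped to [0, 1].
#' @export
#' @examples
#' drift_efficacy(0.9, dt = 1000)  # 1
#' drift_efficacy(0.49, dt = 1000) # 0
drift_efficacy <- function(w, dt, pp = plasticity_params()) {
  stopifnot(dt > 0, all(w >= 0), all(w <= 1))
  up <- w > pp$w_theta
  w[up] <- pmin(1, w[up] + pp$alpha_up * dt)
  w[!up] <- pmax(0, w[!up] - pp$beta_down * dt)
  w
}

#' Decay the postsynaptic calcium trace
#'
#' The trace jumps by \code{ca_jump} at every postsynaptic spike and decays
#' exponentially with time constant \code{tau_ca} in between; it gates the
#' jumps of \code{\link{on_pre_spike}}.
#'
#' @param ca Trace value.
#' @param dt Elapsed time (ms), >= 0.
#' @param pp A \code{\link{plasticity_params}} object.
#' @return The decayed trace.
#' @export
decay_ca <- function(ca, dt, pp = plasticity_params()) {
  stopifnot(all(ca >= 0), dt >= 0)
  ca * exp(-dt / pp$tau_ca)
}
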