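#' Simulate the network
#'
#' Runs the fixed-step simulation of a network built with
#' \code{\link{build_network}}.  The A population can be driven either by
#' per-channel current traces (integrated by the A neurons' LIF dynamics) or
#' by a precomputed A spike raster (the "prepared off-line" convention used
#' for FM-sweep stimuli, see \code{\link{encode_to_spikes}}).  Lateral
#' B1 -> B2 events travel through an event queue with per-synapse delay
#' \eqn{d_0 + |x - y| \nu}; plastic efficacies are updated by the bistable
#' rule only when \code{learning = TRUE}.  The simulation is fully
#' deterministic given its inputs: all stochasticity lives in stimulus
#' generation.
#'
#' @param net A \code{"tononet"} object.
#' @param drive Either a \code{\link{current_traces}} object (or a bare
#'   n_channels x n_samples matrix sampled at the network \code{dt}), or
#'   \code{NULL} when \code{a_spikes} is given.
#' @param a_spikes A \code{\link{spike_raster}} (or data frame with columns
#'   \code{time_ms}, \code{channel}) of forced A spikes; mutually exclusive
#'   with \code{drive}.
#' @param duration Simulation length (ms); defaults to the drive length or
#'   the raster duration.
#' @param learning Enable plasticity (default \code{FALSE}).
#' @param record_a Record A-population spikes in the returned raster
#'   (default \code{TRUE}; turning it off saves memory in long probes).
#' @param record_deliveries Also log every plastic-synapse event delivery
#'   (time, source, target) -- used to verify the delay law.
#' @param seed Optional integer; the simulation itself uses no random
#'   numbers, but the seed is set for interface uniformity with stochastic
#'   callers.
#'
#' @return A list of class \code{"sim_result"}: \code{raster} (a
#'   \code{\link{spike_raster}} of all recorded populations), \code{net}
#'   (the network with post-run efficacies), and, if requested,
#'   \code{deliveries} (data frame \code{time_ms}, \code{x}, \code{y}).
#' @export
simulate_network <- function(net, drive = NULL, a_spikes = NULL,
                             duration = NULL, learning = FALSE,
                             record_a = TRUE, record_deliveries = FALSE,
                             seed = NULL) {
  stopifnot(inherits(net, "tononet"))
  if (!is.null(seed)) set.seed(seed)
  p <- net$params
  if (is.null(drive) == is.null(a_spikes))
    stop("supply exactly one of `drive` or `a_spikes`", call. = FALSE)

  if (!is.null(drive)) {
    if (inherits(drive, "current_traces")) {
      if (abs(drive$dt - p$dt) > 1e-12)
        stop("drive dt (", drive$dt, ") does not match network dt (",
             p$dt, ")", call. = FALSE)
      drive <- drive$values
    }
    drive <- as.matrix(drive)
    if (nrow(drive) != p$n_channels)
      stop("drive has ", nrow(drive), " rows but the network has ",
           p$n_channels, " channels", call. = FALSE)
    if (is.null(duration)) duration <- ncol(drive) * p$dt
    n_steps <- as.integer(round(duration / p$dt))
    if (ncol(drive) < n_steps)
      stop("drive does not cover the requested duration", call. = FALSE)
    drive <- drive[, seq_len(n_steps), drop = FALSE]
    use_drive <- TRUE
    a_step <- integer(); a_ch <- integer()
  } else {
    if (max(a_spikes$channel) > p$n_channels || min(a_spikes$channel) < 1)
      stop("a_spikes channel out of range", call. = FALSE)
    if (is.null(duration)) {
      duration <- attr(a_spikes, "duration")
      if (is.null(duration)) duration <- max(a_spikes$time_ms) + 1
    }
    n_steps <- as.integer(round(duration / p$dt))
    # spike at time t maps to the step whose update it concludes
    a_step <- pmax(0L, as.integer(round(a_spikes$time_ms / p$dt)) - 1L)
    keep <- a_step < n_steps
    a_step <- a_step[keep]
    a_ch <- as.integer(a_spikes$channel)[keep]
    o <- order(a_step, a_ch)
    a_step <- a_step[o]; a_ch <- a_ch[o]
    use_drive <- FALSE
    drive <- matrix(0, p$n_channels, 0)
  }

  delay_steps <- pmax(1L, as.integer(round(net$synapses$delay_ms / p$dt)))
  res <- sim_core(drive, use_drive, a_step, a_ch, n_steps,
                  unclass(net$neuron), unclass(p), unclass(net$plasticity),
                  net$synapses$x, net$synapses$y, delay_steps,
                  net$synapses$w, learning, record_a, record_deliveries)

  pops <- c("A", "B1", "B2")[res$pop + 1L]
  raster <- spike_raster(res$time_ms, pops, res$channel,
                         duration = n_steps * p$dt)
  net$synapses$w <- res$w_final
  out <- list(raster = raster, net = net)
  if (record_deliveries)
    out$deliveries <- data.frame(time_ms = res$del_time,
                                 x = res$del_x, y = res$del_y)
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  print(x$raster)
  cat(sprintf("  mean efficacy after run: %.3f\n", mean(x$net$synapses$w)))
  invisible(x)
}

#' Count spikes of one population per channel or in a time window
#'
#' @param raster A \code{\link{spike_raster}}.
#' @param population Population tag to count (default \code{"B2"}).
#' @param from,to Optional window [from, to) in ms.
#' @return Total spike count (integer).
#' @export
count_spikes <- function(raster, population = "B2", from = -Inf, to = Inf) {
  sum(raster$population == population &
        raster$time_ms >= from & raster$time_ms < to)
}
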