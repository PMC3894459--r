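#' Build a tonotopic A/B1/B2 network
#'
#' Constructs the network: one A (input), one B1 (relay) and one B2 (output)
#' neuron per tonotopic channel.  Within each channel A projects to B1 and B2
#' through fixed excitatory synapses.  Each B1 neuron sends delayed plastic
#' excitatory projections to the B2 neurons of up to \code{fan_out} channels
#' on either side (never its own channel), with transmission delay
#' \eqn{d_0 + |x - y| \nu}; these lateral synapses are the loci of learning
#' and are initialized at zero efficacy ("low" state).  Inhibitory B1 -> B2
#' projections follow \code{params$inhibition_mode}.
#'
#' @param params A \code{\link{network_params}} object.
#' @param neuron A \code{\link{neuron_params}} object.
#' @param plasticity A \code{\link{plasticity_params}} object.
#'
#' @return An object of class \code{"tononet"} with elements
#'   \code{params}, \code{neuron}, \code{plasticity}, and \code{synapses}, a
#'   data frame of the plastic connection list (columns \code{x} source
#'   channel, \code{y} target channel, \code{delay_ms}, \code{w} efficacy).
#' @export
#' @examples
#' net <- build_network(network_params(n_channels = 8, fan_out = 3))
#' nrow(net$synapses)
build_network <- function(params = network_params(),
                          neuron = neuron_params(),
                          plasticity = plasticity_params()) {
  stopifnot(inherits(params, "network_params"),
            inherits(neuron, "neuron_params"),
            inherits(plasticity, "plasticity_params"))
  n <- params$n_channels
  fo <- params$fan_out
  # plastic B1(x) -> B2(y) for 0 < |x - y| <= fan_out, clipped at edges
  x <- rep(seq_len(n), each = 2L * fo)
  off <- rep(c(-(fo:1), 1:fo), times = n)
  y <- x + off
  keep <- y >= 1L & y <= n
  x <- x[keep]; y <- y[keep]
  syn <- data.frame(x = x, y = y,
                    delay_ms = params$d0 + abs(x - y) * params$nu,
                    w = 0)
  structure(list(params = params, neuron = neuron, plasticity = plasticity,
                 synapses = syn),
            class = "tononet")
}

#' Reset a network between experiment phases
#'
#' Membrane state and the pending-event queue live only inside a simulation
#' run, so resetting a network object amounts to (optionally) returning all
#' plastic efficacies to their "low" state of zero, the convention used at
#' the start of every exposure phase.
#'
#' @param net A \code{"tononet"} object.
#' @param weights_low If \code{TRUE} (default) set all plastic efficacies to
#'   0; if \code{FALSE} efficacies are preserved.
#'
#' @return The reset network.  Idempotent.
#' @export
reset_network <- function(net, weights_low = TRUE) {
  stopifnot(inherits(net, "tononet"))
  if (weights_low) net$synapses$w <- 0
  net
}

#' Set plastic efficacies from a connectivity matrix
#'
#' @param net A \code{"tononet"} object.
#' @param w Either a vector of length \code{nrow(net$synapses)} or an
#'   n_channels x n_channels matrix \code{w[x, y]}.
#' @return The network with updated efficacies.
#' @export
set_efficacies <- function(net, w) {
  stopifnot(inherits(net, "tononet"))
  if (is.matrix(w)) {
    stopifnot(nrow(w) == net$params$n_channels,
              ncol(w) == net$params$n_channels)
    w <- w[cbind(net$synapses$x, net$synapses$y)]
  }
  stopifnot(length(w) == nrow(net$synapses), all(w >= 0), all(w <= 1))
  net$synapses$w <- w
  net
}

#' Efficacy snapshot as a channels x channels matrix
#'
#' Arranges the current plastic efficacies as a matrix \code{C[x, y]} (source
#' channel by target channel); pairs without a synapse (self-channel, or
#' beyond the fan-out) are \code{NA} by default.
#'
#' @param net A \code{"tononet"} object.
#' @param fill Value for absent pairs (default \code{NA_real_}; use 0 for a
#'   plottable/writable dense matrix).
#' @return An n x n numeric matrix.
#' @export
efficacy_matrix <- function(net, fill = NA_real_) {
  stopifnot(inherits(net, "tononet"))
  n <- net$params$n_channels
  m <- matrix(fill, n, n)
  m[cbind(net$synapses$x, net$synapses$y)] <- net$synapses$w
  m
}

#' @export
print.tononet <- function(x, ...) {
  p <- x$params
  cat(sprintf("Tonotopic spiking network: %d channels, %d plastic synapses\n",
              p$n_channels, nrow(x$synapses)))
  cat(sprintf("  fan-out %d/side, delays %g + |x-y|*%g ms, inhibition: %s\n",
              p$fan_out, p$d0, p$nu, p$inhibition_mode))
  frac_high <- mean(x$synapses$w > 0.5)
  cat(sprintf("  efficacies: mean %.3f, fraction > 0.5: %.3f\n",
              mean(x$synapses$w), frac_high))
  invisible(x)
}

#' Construct a spike raster
#'
#' The universal simulation output: time-stamped spike events tagged by
#' population (\code{"A"}, \code{"B1"}, \code{"B2"}) and 1-based channel.
#'
#' @param time_ms Numeric vector of spike times (ms), sorted non-decreasing.
#' @param population Character vector of population tags.
#' @param channel Integer vector of channel indices.
#' @param duration Raster duration (ms); all times must lie in
#'   [0, duration].
#' @return A data frame of class \code{"spike_raster"} with attribute
#'   \code{duration}.
#' @export
spike_raster <- function(time_ms = numeric(), population = character(),
                         channel = integer(), duration = 0) {
  stopifnot(length(time_ms) == length(population),
            length(time_ms) == length(channel))
  if (is.unsorted(time_ms)) stop("spike times must be sorted", call. = FALSE)
  if (length(time_ms) && (min(time_ms) < 0 || max(time_ms) > duration))
    stop("spike times must lie within [0, duration]", call. = FALSE)
  r <- data.frame(time_ms = as.numeric(time_ms),
                  population = as.character(population),
                  channel = as.integer(channel))
  attr(r, "duration") <- duration
  class(r) <- c("spike_raster", "data.frame")
  r
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d events over %g ms\n",
              nrow(x), attr(x, "duration")))
  tab <- table(x$population)
  if (length(tab))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
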